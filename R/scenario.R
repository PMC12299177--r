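#' Scenario configuration
#'
#' A scenario bundles every parameter of the exposure chain: source
#' (infiltration coefficient, layer geometry, tailings fraction, density),
#' vadose zone (Darcy velocity, mixing-zone thickness, infiltration rate,
#' road width, partitioning), saturated transport (well distance, hydraulic
#' conductivity, gradient, porosity, dispersion), the precipitation regime,
#' the pollutant inventory, and run settings. Each physical parameter is a
#' [dist_spec] (scalars are promoted to `dist_fixed`); central-value runs
#' resolve normals to their mean and uniforms to their midpoint.
#'
#' Defaults reproduce the base-case study conditions: a humid study area
#' with 900 mm/a precipitation, the standard hydrogeological parameter
#' distributions, and road parameters from highway design ranges (layer
#' thickness U(0.3, 1.2) m, width U(3.5, 30) m, tailings volume fraction
#' U(0.1, 0.5)), with the observation well 100 m downgradient.
#'
#' @param precip_mm_a Annual precipitation, mm/a (`dist_spec` or scalar).
#' @param source Named list: `alpha` (infiltration coefficient, -), `d`
#'   (layer thickness, m), `f` (tailings volume fraction, -), `rho` (layer
#'   density, kg/L), `ls_ratio` (cumulative liquid-to-solid ratio of the
#'   availability test, L/kg, fixed scalar).
#' @param vadose Named list: `Ugw` (m/a), `delta_gw` (m), `I` (m/a), `W`
#'   (m), `Kd` (L/kg), `theta_ws`, `theta_as`, `rho_b` (kg/L), `H` (-).
#' @param transport Named list: `x` (m), `K` (m/d), `i` (-), `n` (-), `DL`
#'   (m^2/d).
#' @param pollutants Tibble as from [default_pollutants()].
#' @param horizon_a Simulation horizon, years.
#' @param dt_a Time-grid step, years.
#' @param c0_mode How the initial leachate concentration links to the
#'   availability-leachate concentration: `"f_cj"` (`C0 = f * Cj`, default)
#'   or `"cj"` (`C0 = Cj`).
#' @param cw_mode How Eq-type well coupling builds the released content
#'   `cw` (mg/kg): `"equilibrium"` (default; soil content in equilibrium
#'   with the pore-water leachate, `cw = Ksw * Ct`, so the well
#'   concentration is `Ct * LFspw_gw * DAF`) or `"inventory"` (full
#'   releasable inventory, `cw = f * Csw * exp(-lambda t)`).
#' @param couple_infiltration If `TRUE`, the vadose infiltration rate `I` is
#'   replaced by `q = alpha * P` so precipitation drives source depletion
#'   and vadose dilution coherently (used by regional scenarios).
#' @param n_iter Default Monte Carlo iterations.
#' @return A `scenario_config` object (nested list).
#' @seealso [load_scenario()], [write_scenario()], [resolve_central()]
#' @export
scenario_config <- function(precip_mm_a = dist_fixed(900),
                            source = list(),
                            vadose = list(),
                            transport = list(),
                            pollutants = default_pollutants(),
                            horizon_a = 50,
                            dt_a = 0.05,
                            c0_mode = c("f_cj", "cj"),
                            cw_mode = c("equilibrium", "inventory"),
                            couple_infiltration = FALSE,
                            n_iter = 10000) {
  c0_mode <- match.arg(c0_mode)
  cw_mode <- match.arg(cw_mode)

  src_def <- list(alpha = dist_normal(0.2, 0.05),
                  d = dist_uniform(0.3, 1.2),
                  f = dist_uniform(0.1, 0.5),
                  rho = dist_normal(2, 0.2),
                  ls_ratio = 100)
  vad_def <- list(Ugw = dist_fixed(25),
                  delta_gw = dist_normal(2, 0.082),
                  I = dist_fixed(0.3),
                  W = dist_uniform(3.5, 30),
                  Kd = dist_fixed(0),
                  theta_ws = dist_fixed(0.3),
                  theta_as = dist_fixed(0.2),
                  rho_b = dist_fixed(1.5),
                  H = dist_fixed(0))
  tra_def <- list(x = dist_fixed(100),
                  K = dist_uniform(10, 50),
                  i = dist_uniform(0.003, 0.006),
                  n = dist_uniform(0.30, 0.50),
                  DL = dist_uniform(5, 10))

  merge_group <- function(def, given, group) {
    unknown <- setdiff(names(given), names(def))
    if (length(unknown) > 0) {
      abort(paste0("unknown ", group, " parameter(s): ",
                   paste(unknown, collapse = ", ")),
            class = "tailrisk_schema_error")
    }
    out <- modifyList(def, given)
    lapply(out, as_dist)
  }

  sc <- structure(list(
    precip_mm_a = as_dist(precip_mm_a),
    source = merge_group(src_def, source, "source"),
    vadose = merge_group(vad_def, vadose, "vadose"),
    transport = merge_group(tra_def, transport, "transport"),
    pollutants = tibble::as_tibble(pollutants),
    horizon_a = horizon_a,
    dt_a = dt_a,
    c0_mode = c0_mode,
    cw_mode = cw_mode,
    couple_infiltration = isTRUE(couple_infiltration),
    n_iter = as.integer(n_iter)
  ), class = "scenario_config")
  validate_scenario(sc)
  sc
}

#' @rdname scenario_config
#' @export
default_scenario <- function() scenario_config()

validate_scenario <- function(sc) {
  chk <- function(cond, msg) {
    if (!cond) abort(msg, class = "tailrisk_validation_error")
  }
  cen <- function(x) dist_central(x)
  chk(cen(sc$precip_mm_a) >= 0, "precipitation must be >= 0 mm/a")
  chk(cen(sc$source$d) > 0, "subgrade thickness d must be > 0 m")
  f <- cen(sc$source$f)
  chk(f >= 0 && f <= 1, "tailings volume fraction f must be in [0, 1]")
  chk(cen(sc$source$rho) > 0, "subgrade density rho must be > 0 kg/L")
  chk(cen(sc$source$ls_ratio) > 0, "ls_ratio must be > 0 L/kg")
  chk(cen(sc$vadose$rho_b) > 0, "soil bulk density rho_b must be > 0 kg/L")
  chk(cen(sc$vadose$theta_ws) + cen(sc$vadose$theta_as) <= 1,
      "theta_ws + theta_as must be <= 1")
  chk(cen(sc$vadose$W) > 0, "road width W must be > 0 m")
  chk(cen(sc$vadose$I) > 0 || sc$couple_infiltration,
      "infiltration rate I must be > 0 m/a")
  chk(cen(sc$transport$x) > 0, "well distance x must be > 0 m")
  nn <- cen(sc$transport$n)
  chk(nn > 0 && nn < 1, "porosity n must be in (0, 1)")
  chk(cen(sc$transport$DL) > 0, "dispersion coefficient DL must be > 0 m^2/d")
  chk(sc$horizon_a > 0 && sc$dt_a > 0 && sc$dt_a < sc$horizon_a,
      "need 0 < dt_a < horizon_a")
  chk(sc$n_iter >= 1, "n_iter must be >= 1")
  req <- c("pollutant", "class3_limit", "mean", "sd")
  chk(all(req %in% names(sc$pollutants)),
      "pollutants table needs columns pollutant, class3_limit, mean, sd")
  chk(all(sc$pollutants$class3_limit > 0), "class3_limit must be > 0")
  invisible(sc)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat("  precipitation:", format(x$precip_mm_a), "mm/a",
      if (x$couple_infiltration) "(infiltration coupled to alpha*P)" else "", "\n")
  for (g in c("source", "vadose", "transport")) {
    cat("  ", g, ": ", paste0(names(x[[g]]), " = ",
        vapply(x[[g]], format, character(1)), collapse = ", "), "\n", sep = "")
  }
  cat("  pollutants:", paste(x$pollutants$pollutant, collapse = ", "), "\n")
  cat("  horizon:", x$horizon_a, "a, dt:", x$dt_a,
      "a, c0_mode:", x$c0_mode, ", cw_mode:", x$cw_mode,
      ", n_iter:", x$n_iter, "\n")
  invisible(x)
}

#' Expected units of scenario parameters
#'
#' Unit annotations accepted (and validated) in YAML scenario files.
#'
#' @return A tibble with columns `group`, `field`, `unit`.
#' @export
scenario_units <- function() {
  tibble::tribble(
    ~group,      ~field,      ~unit,
    "top",       "precip_mm_a", "mm/a",
    "source",    "alpha",     "-",
    "source",    "d",         "m",
    "source",    "f",         "-",
    "source",    "rho",       "kg/L",
    "source",    "ls_ratio",  "L/kg",
    "vadose",    "Ugw",       "m/a",
    "vadose",    "delta_gw",  "m",
    "vadose",    "I",         "m/a",
    "vadose",    "W",         "m",
    "vadose",    "Kd",        "L/kg",
    "vadose",    "theta_ws",  "-",
    "vadose",    "theta_as",  "-",
    "vadose",    "rho_b",     "kg/L",
    "vadose",    "H",         "-",
    "transport", "x",         "m",
    "transport", "K",         "m/d",
    "transport", "i",         "-",
    "transport", "n",         "-",
    "transport", "DL",        "m^2/d"
  )
}

# a YAML field is a scalar, or a map with dist keys and an optional `unit`
# annotation checked against scenario_units()
field_from_yaml <- function(value, group, field) {
  units <- scenario_units()
  expected <- units$unit[units$group == group & units$field == field]
  if (is.list(value) && !is.null(value$unit)) {
    if (length(expected) == 1 && !identical(value$unit, expected)) {
      abort(sprintf("field %s/%s has unit '%s'; expected '%s'",
                    group, field, value$unit, expected),
            class = "tailrisk_validation_error")
    }
    value$unit <- NULL
    if (identical(names(value), "value") || length(value) == 1 && !is.null(value$value)) {
      value <- value$value
    }
  }
  as_dist(value)
}

#' Read a scenario configuration from YAML
#'
#' Unknown keys raise a schema error; every field may be a scalar, or a map
#' `{kind: normal|uniform|fixed, ...}` with an optional `unit` annotation
#' validated against [scenario_units()]. Missing fields are filled with the
#' base-case defaults of [scenario_config()].
#'
#' @param path Path to a YAML file.
#' @return A `scenario_config`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("scenario file not found: ", path), class = "tailrisk_io_error")
  }
  raw <- yaml::read_yaml(path)
  known <- c("schema", "precip_mm_a", "source", "vadose", "transport",
             "pollutants", "horizon_a", "dt_a", "c0_mode", "cw_mode",
             "couple_infiltration", "n_iter")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown scenario key(s): ", paste(unknown, collapse = ", ")),
          class = "tailrisk_schema_error")
  }
  if (!is.null(raw$schema) && !identical(raw$schema, "tailrisk/1")) {
    abort(paste0("unsupported schema version: ", raw$schema),
          class = "tailrisk_schema_error")
  }
  parse_group <- function(group) {
    g <- raw[[group]]
    if (is.null(g)) return(list())
    lapply(setNames(names(g), names(g)),
           function(f) field_from_yaml(g[[f]], group, f))
  }
  args <- list(
    source = parse_group("source"),
    vadose = parse_group("vadose"),
    transport = parse_group("transport")
  )
  if (!is.null(raw$precip_mm_a)) {
    args$precip_mm_a <- field_from_yaml(raw$precip_mm_a, "top", "precip_mm_a")
  }
  if (!is.null(raw$pollutants)) {
    args$pollutants <- dplyr::bind_rows(lapply(raw$pollutants, tibble::as_tibble))
  }
  for (k in c("horizon_a", "dt_a", "c0_mode", "cw_mode",
              "couple_infiltration", "n_iter")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  do.call(scenario_config, args)
}

#' Write a scenario configuration to YAML
#'
#' Round-trips through [load_scenario()]: `load_scenario(write_scenario(sc,
#' path))` reproduces `sc`.
#'
#' @param scenario A `scenario_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_config"))
  ser_group <- function(g) lapply(g, dist_to_list)
  doc <- list(
    schema = "tailrisk/1",
    precip_mm_a = dist_to_list(scenario$precip_mm_a),
    source = ser_group(scenario$source),
    vadose = ser_group(scenario$vadose),
    transport = ser_group(scenario$transport),
    pollutants = lapply(seq_len(nrow(scenario$pollutants)), function(i) {
      as.list(scenario$pollutants[i, ])
    }),
    horizon_a = scenario$horizon_a,
    dt_a = scenario$dt_a,
    c0_mode = scenario$c0_mode,
    cw_mode = scenario$cw_mode,
    couple_infiltration = scenario$couple_infiltration,
    n_iter = scenario$n_iter
  )
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Resolve a scenario to central parameter values
#'
#' Collapses every distribution to its central value (normal mean, uniform
#' midpoint, fixed value) for deterministic runs. The leachate concentration
#' `cj` is taken from the pollutant's fitted distribution mean unless
#' supplied.
#'
#' @param scenario A `scenario_config`.
#' @param pollutant Pollutant label (row of `scenario$pollutants`).
#' @param cj Optional override of the leachate concentration, mg/L.
#' @return A named list of scalar parameters (see [exposure_timeseries()]).
#' @export
resolve_central <- function(scenario, pollutant, cj = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  spec <- pollutant_spec(scenario, pollutant)
  vals <- c(
    list(precip = dist_central(scenario$precip_mm_a) / 1000),
    lapply(scenario$source, dist_central),
    lapply(scenario$vadose, dist_central),
    lapply(scenario$transport, dist_central)
  )
  vals$cj <- cj %||% spec$mean
  vals$pollutant <- pollutant
  vals$class3_limit <- spec$class3_limit
  vals
}

pollutant_spec <- function(scenario, pollutant) {
  row <- scenario$pollutants[scenario$pollutants$pollutant == pollutant, ]
  if (nrow(row) != 1) {
    abort(paste0("pollutant not in scenario: ", pollutant),
          class = "tailrisk_lookup_error")
  }
  row
}

#' Fix one scenario parameter at a value
#'
#' Overrides a (possibly distribution-valued) parameter with a fixed scalar;
#' used by the blend-ratio sweep to pin the tailings volume fraction.
#'
#' @param scenario A `scenario_config`.
#' @param group One of `"source"`, `"vadose"`, `"transport"`, `"precip"`.
#' @param field Parameter name inside the group (ignored for `"precip"`).
#' @param value Fixed value.
#' @return The modified `scenario_config`.
#' @export
fix_parameter <- function(scenario, group, field = NULL, value) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (group == "precip") {
    scenario$precip_mm_a <- dist_fixed(value)
  } else {
    if (!group %in% c("source", "vadose", "transport")) {
      abort("unknown parameter group", class = "tailrisk_schema_error")
    }
    if (!field %in% names(scenario[[group]])) {
      abort(paste0("unknown field ", field, " in ", group),
            class = "tailrisk_schema_error")
    }
    scenario[[group]][[field]] <- dist_fixed(value)
  }
  validate_scenario(scenario)
  scenario
}
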