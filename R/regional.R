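#' Dry-wet climate regimes
#'
#' China's four annual-precipitation classes: humid (> 800 mm), semi-humid
#' (400-800 mm), semi-arid (200-400 mm) and arid (< 200 mm); within a
#' regime, precipitation is uniformly distributed. The open-ended classes
#' are closed at 1600 mm (humid) and 25 mm (arid) — configurable choices
#' documented in the methods vignette.
#'
#' @param name One of `"humid"`, `"semi_humid"`, `"semi_arid"`, `"arid"`.
#' @param humid_upper,arid_lower Closure bounds for the open-ended regimes,
#'   mm/a.
#' @return A `dist_spec` for annual precipitation in mm/a.
#' @export
#' @examples
#' regime_precipitation("semi_humid") # U(400, 800) mm/a
regime_precipitation <- function(name, humid_upper = 1600, arid_lower = 25) {
  bounds <- list(
    humid      = c(800, humid_upper),
    semi_humid = c(400, 800),
    semi_arid  = c(200, 400),
    arid       = c(arid_lower, 200)
  )
  if (!name %in% names(bounds)) {
    abort(paste0("unknown climate regime: ", name,
                 " (expected humid, semi_humid, semi_arid or arid)"),
          class = "tailrisk_lookup_error")
  }
  b <- bounds[[name]]
  dist_uniform(b[1], b[2])
}

#' Apply a climate regime to a scenario
#'
#' Sets the precipitation distribution to the regime's uniform band and
#' couples the vadose infiltration rate to `alpha * P`, so precipitation
#' drives both source depletion and vadose dilution.
#'
#' @param scenario A [scenario_config()].
#' @param regime Regime name (see [regime_precipitation()]) or a
#'   `dist_spec` in mm/a.
#' @return The modified `scenario_config`.
#' @export
set_regime <- function(scenario, regime) {
  stopifnot(inherits(scenario, "scenario_config"))
  scenario$precip_mm_a <- if (is_dist_spec(regime)) regime else regime_precipitation(regime)
  scenario$couple_infiltration <- TRUE
  validate_scenario(scenario)
  scenario
}

#' Run a regional scenario
#'
#' For one climate regime and pollutant: (1) a deterministic
#' central-parameter run with precipitation at the regime mean, giving the
#' well-concentration time series and its peak; (2) a Monte Carlo run with
#' precipitation drawn from the regime's uniform band, giving the risk
#' summary. In both, the infiltration rate is coupled to `alpha * P`.
#'
#' @param scenario Base [scenario_config()].
#' @param regime Regime name (see [regime_precipitation()]).
#' @param pollutant Pollutant label.
#' @param n_iter Monte Carlo iterations.
#' @param seed Integer seed.
#' @return A `regional_result`: list with `series` (central
#'   `exposure_series`), `central_peak` (one-row tibble), `mc`
#'   (`mc_result`), `summary` (tibble), `regime`, `pollutant`.
#' @export
#' @examples
#' r <- run_regional_scenario(default_scenario(), "humid", "Ni",
#'                            n_iter = 100, seed = 3)
#' r$central_peak
run_regional_scenario <- function(scenario, regime, pollutant,
                                  n_iter = scenario$n_iter, seed = 1L) {
  sc <- set_regime(scenario, regime)
  series <- exposure_timeseries(sc, pollutant)
  mc <- run_monte_carlo(sc, pollutant, n_iter = n_iter, seed = seed)
  structure(list(
    series = series,
    central_peak = peak_exposure(series),
    mc = mc,
    summary = summarize_mc(mc),
    regime = if (is_dist_spec(regime)) format(regime) else regime,
    pollutant = pollutant
  ), class = "regional_result")
}

#' @export
print.regional_result <- function(x, ...) {
  cat(sprintf("<regional_result> %s, %s regime\n", x$pollutant, x$regime))
  cat(sprintf("  central-run peak: %.4g mg/L at year %.2f (ratio to limit %.3g)\n",
              x$central_peak$peak_mg_L, x$central_peak$peak_time_a,
              x$central_peak$ratio_to_standard))
  cat(sprintf("  MC (n = %d): exceedance %.3f, p95 %.4g mg/L\n",
              x$mc$n_iter, x$summary$exceed_prob, x$summary$p95))
  invisible(x)
}

#' Blend-ratio management sweep
#'
#' Sweeps the tailings volume fraction `f` over a grid, fixing `f` at each
#' value (overriding its distribution) and running the Monte Carlo
#' simulation under the given climate regime with the same seed (common
#' random numbers, so the sweep is smooth in `f`). The risk metric per `f`
#' is the exposure concentration — by default the 95th-percentile peak —
#' divided by the Class III limit; `f_max` is the largest grid fraction
#' whose ratio stays at or below 1.
#'
#' @param scenario Base [scenario_config()].
#' @param regime Regime name.
#' @param pollutant Pollutant label.
#' @param f_grid Grid of volume fractions in (0, 1].
#' @param n_iter Monte Carlo iterations per grid point.
#' @param seed Integer seed (shared across grid points).
#' @param metric `"p95"` (default, the study convention) or `"central"`
#'   (deterministic central-parameter peak).
#' @return A `blend_sweep` tibble with columns `f`, `exposure_conc_mg_L`,
#'   `ratio_to_standard`, `exceed_prob`; attributes `f_max`, `regime`,
#'   `pollutant`, `metric`.
#' @export
#' @examples
#' bs <- blend_sweep(default_scenario(), "semi_humid", "Mn",
#'                   f_grid = c(0.2, 0.6, 1), n_iter = 100, seed = 3)
#' attr(bs, "f_max")
blend_sweep <- function(scenario, regime, pollutant,
                        f_grid = seq(0.05, 1, by = 0.05),
                        n_iter = scenario$n_iter, seed = 1L,
                        metric = c("p95", "central")) {
  metric <- match.arg(metric)
  if (length(f_grid) == 0) {
    abort("`f_grid` must be non-empty", class = "tailrisk_validation_error")
  }
  if (any(f_grid <= 0) || any(f_grid > 1)) {
    abort("`f_grid` values must lie in (0, 1]", class = "tailrisk_validation_error")
  }
  f_grid <- sort(f_grid)
  sc0 <- set_regime(scenario, regime)
  spec <- pollutant_spec(scenario, pollutant)
  rows <- purrr::map_dfr(f_grid, function(f) {
    sc <- fix_parameter(sc0, "source", "f", f)
    if (metric == "p95") {
      s <- summarize_mc(run_monte_carlo(sc, pollutant, n_iter = n_iter, seed = seed))
      tibble::tibble(f = f, exposure_conc_mg_L = s$p95,
                     ratio_to_standard = s$p95 / spec$class3_limit,
                     exceed_prob = s$exceed_prob)
    } else {
      pk <- peak_exposure(exposure_timeseries(sc, pollutant))
      tibble::tibble(f = f, exposure_conc_mg_L = pk$peak_mg_L,
                     ratio_to_standard = pk$ratio_to_standard,
                     exceed_prob = NA_real_)
    }
  })
  ok <- rows$f[rows$ratio_to_standard <= 1]
  f_max <- if (length(ok) == 0) NA_real_ else max(ok)
  if (is.na(f_max)) {
    warn(sprintf("%s/%s: exposure exceeds the standard at every grid fraction",
                 pollutant, if (is_dist_spec(regime)) format(regime) else regime))
  }
  structure(rows, class = c("blend_sweep", class(rows)),
            f_max = f_max, regime = if (is_dist_spec(regime)) format(regime) else regime,
            pollutant = pollutant, metric = metric)
}
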