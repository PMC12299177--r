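YEAR_DAYS <- 365  # exact year <-> day conversion used throughout

# shared per-draw derived quantities; params is a named list (scalars) or a
# data frame of draws (vector fields). Returns list of vectors.
derive_factors <- function(params, c0_mode, cw_mode, couple_infiltration) {
  q <- params$alpha * params$precip               # net infiltration, m/a
  csw <- availability_from_leachate(params$cj, params$ls_ratio)
  c0 <- switch(c0_mode, f_cj = params$f * params$cj, cj = params$cj)
  active <- params$f > 0 & params$cj > 0 & q > 0
  lam <- ifelse(active,
                q / (params$d * params$f * params$rho * params$ls_ratio),
                0)  # = q*cj/(d f rho Csw); cj cancels against Csw = cj*ls
  ksw <- soil_water_partition(params$theta_ws, params$Kd, params$rho_b,
                              params$H, params$theta_as)
  I_eff <- if (couple_infiltration) q else params$I + 0 * q
  lfsp <- ifelse(I_eff > 0,
                 spw_to_gw_factor(params$Ugw, params$delta_gw,
                                  pmax(I_eff, 1e-300), params$W),
                 0)
  u <- seepage_velocity(params$K, params$i, params$n)
  list(q = q, csw = csw, c0 = c0, lam = lam, ksw = ksw, lfsp = lfsp,
       lf = lfsp / ksw, u = u, active = active)
}

#' Observation-well concentration time series
#'
#' Couples source depletion, vadose leaching and saturated transport into
#' the well concentration `cgw(t) = cw(t) * LF * DAF(t)`, where `cw` is the
#' released solid-phase content (mg/kg), `LF` the soil leaching/dilution
#' factor (kg/L) and `DAF` the transport dilution-attenuation factor. Under
#' the default `cw_mode = "equilibrium"` the content is the soil
#' concentration in equilibrium with the pore-water leachate
#' (`cw = Ksw * Ct`), so `cgw = Ct * LFspw_gw * DAF`; under `"inventory"`
#' the full releasable inventory `f * Csw * exp(-lambda t)` is used.
#'
#' @param scenario A [scenario_config()].
#' @param pollutant Pollutant label.
#' @param times Time grid in years (default `seq(dt_a, horizon_a, dt_a)`).
#' @param cj Optional leachate-concentration override, mg/L.
#' @return An `exposure_series` tibble with columns `time_a`, `ct_mg_L`
#'   (source leachate), `cw_mg_kg`, `daf`, `cgw_mg_L`; the resolved
#'   parameters are attached as attributes.
#' @export
#' @examples
#' sc <- default_scenario()
#' head(exposure_timeseries(sc, "Ni"))
exposure_timeseries <- function(scenario, pollutant, times = NULL, cj = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  times <- times %||% seq(scenario$dt_a, scenario$horizon_a, by = scenario$dt_a)
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be non-negative and strictly increasing",
          class = "tailrisk_validation_error")
  }
  p <- resolve_central(scenario, pollutant, cj = cj)
  fct <- derive_factors(p, scenario$c0_mode, scenario$cw_mode,
                        scenario$couple_infiltration)
  ct <- source_concentration(fct$c0, fct$lam, times)
  cw <- switch(scenario$cw_mode,
    equilibrium = fct$ksw * ct,
    inventory   = p$f * fct$csw * exp(-fct$lam * times)
  )
  daf <- dilution_attenuation_factor(p$x, fct$u, p$DL, times * YEAR_DAYS)
  cgw <- if (fct$active) cw * fct$lf * daf else rep(0, length(times))
  out <- tibble::tibble(time_a = times, ct_mg_L = ct, cw_mg_kg = cw,
                        daf = daf, cgw_mg_L = cgw)
  class(out) <- c("exposure_series", class(out))
  attr(out, "pollutant") <- pollutant
  attr(out, "class3_limit") <- p$class3_limit
  attr(out, "params") <- p
  attr(out, "factors") <- fct
  out
}

#' Well concentration from its three factors
#'
#' The elementary coupling `cgw = cw * LF * DAF` (mg/kg x kg/L x 1 = mg/L);
#' exposed for composing externally computed factors.
#'
#' @param cw Released content, mg/kg.
#' @param LF Leaching/dilution factor, kg/L.
#' @param DAF Dilution-attenuation factor, dimensionless.
#' @return Well concentration, mg/L.
#' @export
well_concentration <- function(cw, LF, DAF) cw * LF * DAF

#' Peak exposure over a time series
#'
#' The per-realisation risk metric: the temporal maximum of the well
#' concentration, its timing, and the ratio to the Class III limit.
#'
#' @param series An `exposure_series` from [exposure_timeseries()].
#' @param class3_limit Standard limit, mg/L; defaults to the one attached to
#'   the series.
#' @return A one-row tibble: `pollutant`, `peak_mg_L`, `peak_time_a`,
#'   `ratio_to_standard`.
#' @export
peak_exposure <- function(series, class3_limit = NULL) {
  if (!is.data.frame(series) || nrow(series) == 0) {
    abort("`series` must be a non-empty exposure series",
          class = "tailrisk_validation_error")
  }
  limit <- class3_limit %||% attr(series, "class3_limit")
  k <- which.max(series$cgw_mg_L)
  tibble::tibble(
    pollutant = attr(series, "pollutant") %||% NA_character_,
    peak_mg_L = series$cgw_mg_L[k],
    peak_time_a = series$time_a[k],
    ratio_to_standard = if (is.null(limit)) NA_real_ else series$cgw_mg_L[k] / limit
  )
}

# Vectorised peaks for Monte Carlo: draws is a tibble with one column per
# parameter (all lengths n); returns tibble(peak_mg_L, peak_time_a).
# Works in chunks so the n_draw x n_time DAF matrix stays small.
peaks_over_draws <- function(draws, scenario, times = NULL, chunk = 1000L) {
  times <- times %||% seq(scenario$dt_a, scenario$horizon_a, by = scenario$dt_a)
  t_d <- times * YEAR_DAYS
  n <- nrow(draws)
  peak <- numeric(n)
  peak_t <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d <- draws[idx, ]
    fct <- derive_factors(d, scenario$c0_mode, scenario$cw_mode,
                          scenario$couple_infiltration)
    daf <- daf_matrix(d$x, fct$u, d$DL, t_d)
    decay <- exp(-outer(fct$lam, times))
    amp <- switch(scenario$cw_mode,
      equilibrium = fct$c0 * fct$lfsp,
      inventory   = d$f * fct$csw * fct$lf
    )
    cgw <- (amp * fct$active) * decay * daf
    k <- max.col(cgw, ties.method = "first")
    peak[idx] <- cgw[cbind(seq_along(idx), k)]
    peak_t[idx] <- times[k]
  }
  tibble::tibble(peak_mg_L = peak, peak_time_a = peak_t)
}
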