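# canonical sampling order: one independent RNG substream per symbol, seeded
# from the master seed, so (a) results are identical for a given (seed,
# config) and (b) the first n draws of every symbol are unchanged when
# n_iter grows (prefix stability)
mc_symbols <- function() {
  c("precip_mm_a", "alpha", "d", "f", "rho", "ls_ratio",
    "Ugw", "delta_gw", "I", "W", "Kd", "theta_ws", "theta_as", "rho_b", "H",
    "x", "K", "i", "n", "DL", "cj")
}

#' Sample the scenario parameter space
#'
#' Draws `n_iter` joint realisations of every scenario parameter (fixed
#' parameters are replicated) plus the pollutant's leachate concentration
#' `cj` from its fitted truncated-normal distribution. Each symbol uses its
#' own RNG substream derived from `seed` in the fixed order given by the
#' internal symbol table, so draw matrices are reproducible and
#' prefix-stable in `n_iter`.
#'
#' @param scenario A [scenario_config()].
#' @param pollutant Pollutant label (sets the `cj` distribution).
#' @param n_iter Number of draws.
#' @param seed Integer master seed.
#' @param cj_dist Optional `dist_spec` overriding the leachate distribution.
#' @return A tibble with `n_iter` rows; precipitation is returned both as
#'   `precip_mm_a` (mm/a, as specified) and `precip` (m/a, as consumed by
#'   the exposure engine).
#' @export
sample_parameters <- function(scenario, pollutant, n_iter = scenario$n_iter,
                              seed = 1L, cj_dist = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  n_iter <- as.integer(n_iter)
  if (n_iter < 1) abort("n_iter must be >= 1", class = "tailrisk_validation_error")
  spec <- pollutant_spec(scenario, pollutant)
  cj_dist <- cj_dist %||% dist_normal(spec$mean, spec$sd)

  dists <- c(
    list(precip_mm_a = scenario$precip_mm_a),
    scenario$source, scenario$vadose, scenario$transport,
    list(cj = as_dist(cj_dist))
  )
  symbols <- mc_symbols()
  stopifnot(setequal(names(dists), symbols))

  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(s)
    expr
  }
  draws <- withr_seed(as.integer(seed), {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, length(symbols))
    purrr::map2(symbols, sub_seeds, function(sym, s) {
      set.seed(s)
      dist_sample(dists[[sym]], n_iter)
    })
  })
  names(draws) <- symbols
  out <- tibble::as_tibble(draws)
  out$precip <- out$precip_mm_a / 1000
  out
}

#' Run the Monte Carlo exposure simulation
#'
#' Propagates the scenario parameter distributions and the pollutant's
#' leachate-concentration distribution through the full exposure chain,
#' recording the temporal peak well concentration of each iteration over the
#' scenario horizon.
#'
#' @inheritParams sample_parameters
#' @return An `mc_result`: list with `peaks` (tibble `iter`, `peak_mg_L`,
#'   `peak_time_a`), `pollutant`, `class3_limit`, `n_iter`, `seed`, and the
#'   scenario.
#' @export
#' @examples
#' res <- run_monte_carlo(default_scenario(), "Mn", n_iter = 200, seed = 7)
#' glance(res)
run_monte_carlo <- function(scenario, pollutant, n_iter = scenario$n_iter,
                            seed = 1L, cj_dist = NULL) {
  draws <- sample_parameters(scenario, pollutant, n_iter = n_iter,
                             seed = seed, cj_dist = cj_dist)
  peaks <- peaks_over_draws(draws, scenario)
  bad <- which(!is.finite(peaks$peak_mg_L) | peaks$peak_mg_L < 0)
  if (length(bad) > 0) {
    abort(paste0("non-finite peak concentration at iteration(s) ",
                 paste(utils::head(bad, 5), collapse = ", "),
                 "; offending draw: ",
                 paste(utils::capture.output(print(draws[bad[1], ])), collapse = " ")),
          class = "tailrisk_mc_error")
  }
  spec <- pollutant_spec(scenario, pollutant)
  structure(list(
    peaks = tibble::tibble(iter = seq_len(nrow(peaks)),
                           peak_mg_L = peaks$peak_mg_L,
                           peak_time_a = peaks$peak_time_a),
    pollutant = pollutant,
    class3_limit = spec$class3_limit,
    n_iter = as.integer(n_iter),
    seed = as.integer(seed),
    scenario = scenario
  ), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  s <- summarize_mc(x)
  cat(sprintf("<mc_result> %s: %d iterations (seed %d)\n",
              x$pollutant, x$n_iter, x$seed))
  cat(sprintf("  peak concentration p50/p95/p99: %.4g / %.4g / %.4g mg/L\n",
              s$p50, s$p95, s$p99))
  cat(sprintf("  P(peak > %.3g mg/L) = %.3f; p95/limit = %.3g\n",
              x$class3_limit, s$exceed_prob, s$exceed_multiple))
  invisible(x)
}

#' Summarise a Monte Carlo result
#'
#' Empirical percentiles (linear interpolation), the exceedance probability
#' (fraction of iteration peaks above the Class III limit), and the
#' exceedance multiple (95th-percentile peak divided by the limit — the
#' study's "exposure concentration" convention).
#'
#' @param res An `mc_result`.
#' @param percentiles Probabilities for the quantile columns.
#' @return A one-row tibble.
#' @export
summarize_mc <- function(res, percentiles = c(0.5, 0.95, 0.99)) {
  stopifnot(inherits(res, "mc_result"))
  if (nrow(res$peaks) == 0) {
    abort("empty Monte Carlo result", class = "tailrisk_validation_error")
  }
  qs <- stats::quantile(res$peaks$peak_mg_L, percentiles, names = FALSE, type = 7)
  out <- tibble::tibble(
    pollutant = res$pollutant,
    n_iter = res$n_iter,
    mean_peak = mean(res$peaks$peak_mg_L),
    exceed_prob = mean(res$peaks$peak_mg_L > res$class3_limit),
    class3_limit = res$class3_limit
  )
  for (j in seq_along(percentiles)) {
    out[[sprintf("p%g", 100 * percentiles[j])]] <- qs[j]
  }
  p95 <- stats::quantile(res$peaks$peak_mg_L, 0.95, names = FALSE, type = 7)
  out$exposure_conc <- p95
  out$exceed_multiple <- p95 / res$class3_limit
  out
}

#' @rdname summarize_mc
#' @param x An `mc_result`.
#' @param ... Unused.
#' @export
glance.mc_result <- function(x, ...) summarize_mc(x)

#' Empirical CDF of Monte Carlo peak concentrations
#'
#' @param x An `mc_result`.
#' @param ... Unused.
#' @return A tibble `conc_mg_L`, `cum_freq` suitable for cumulative
#'   frequency plots and CSV export.
#' @export
tidy.mc_result <- function(x, ...) {
  p <- sort(x$peaks$peak_mg_L)
  tibble::tibble(conc_mg_L = p, cum_freq = seq_along(p) / length(p))
}
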