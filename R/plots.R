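#' Plot an exposure time series
#'
#' Well concentration versus time, with the Class III limit as a dashed
#' reference line.
#'
#' @param object An `exposure_series` from [exposure_timeseries()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exposure_series <- function(object, ...) {
  limit <- attr(object, "class3_limit")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_a, y = .data$cgw_mg_L)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "Time since construction (a)",
      y = "Well concentration (mg/L)",
      title = paste0(attr(object, "pollutant") %||% "", " exposure at observation well")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(limit)) {
    p <- p + ggplot2::geom_hline(yintercept = limit, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Plot a Monte Carlo cumulative frequency curve
#'
#' Empirical CDF of per-iteration peak well concentrations, with the Class
#' III limit marked; the crossing height is one minus the exceedance
#' probability.
#'
#' @param object An `mc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_result <- function(object, ...) {
  cdf <- tidy(object)
  ggplot2::ggplot(cdf, ggplot2::aes(x = .data$conc_mg_L, y = .data$cum_freq)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$class3_limit,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Peak well concentration (mg/L, log scale)",
      y = "Cumulative frequency",
      title = sprintf("%s: %d Monte Carlo iterations", object$pollutant, object$n_iter)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a blend-ratio sweep
#'
#' Exposure-to-standard ratio versus tailings volume fraction; the
#' management limit is the largest fraction below the ratio-1 line.
#'
#' @param object A `blend_sweep` from [blend_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blend_sweep <- function(object, ...) {
  f_max <- attr(object, "f_max")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$f, y = .data$ratio_to_standard)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "Tailings volume fraction f",
      y = "Exposure concentration / Class III limit",
      title = sprintf("%s blend sweep, %s regime",
                      attr(object, "pollutant"), attr(object, "regime"))
    ) +
    ggplot2::theme_minimal()
  if (!is.na(f_max)) {
    p <- p + ggplot2::geom_vline(xintercept = f_max, linetype = "dotted")
  }
  p
}
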