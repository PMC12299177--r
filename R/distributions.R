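#' Distribution specifications for uncertain parameters
#'
#' Every scenario parameter is either a fixed scalar or a distribution:
#' normal (optionally truncated below, default at zero), uniform, or fixed
#' (degenerate). These constructors build the spec objects used throughout
#' the scenario configuration and the Monte Carlo engine.
#'
#' Truncated-normal draws use the inverse-CDF method on the conditional
#' probability scale, so a draw stream is an exact prefix of any longer
#' stream from the same seed (required for reproducible Monte Carlo
#' extension) and no rejection loop is needed.
#'
#' @param value Fixed value.
#' @param mean,sd Normal mean and standard deviation (`sd >= 0`).
#' @param lower Lower truncation bound for the normal; default `0`. Use
#'   `-Inf` for an untruncated normal.
#' @param low,high Uniform bounds, `low <= high`.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_normal(0.2, 0.05)
#' dist_uniform(0.3, 1.2)
#' dist_fixed(0.3)
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(kind = "fixed", value = value), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd, lower = 0) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L, length(sd) == 1L)
  if (sd < 0) stop("dist_normal(): `sd` must be >= 0", call. = FALSE)
  structure(list(kind = "normal", mean = mean, sd = sd, lower = lower),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L, length(high) == 1L)
  if (low > high) stop("dist_uniform(): `low` must be <= `high`", call. = FALSE)
  structure(list(kind = "uniform", low = low, high = high), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.dist_spec <- function(x, ...) {
  switch(x$kind,
    fixed   = sprintf("fixed(%g)", x$value),
    normal  = if (is.finite(x$lower)) {
      sprintf("N(%g, %g) truncated at %g", x$mean, x$sd, x$lower)
    } else {
      sprintf("N(%g, %g)", x$mean, x$sd)
    },
    uniform = sprintf("U(%g, %g)", x$low, x$high)
  )
}

#' Test for a distribution spec
#' @param x Object.
#' @return Logical scalar.
#' @export
is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Coerce a value to a distribution spec
#'
#' Scalars become `dist_fixed()`; lists with a `kind` field (as read from a
#' YAML scenario) are rebuilt into the corresponding spec.
#'
#' @param x Numeric scalar, `dist_spec`, or list.
#' @return A `dist_spec`.
#' @export
as_dist <- function(x) {
  if (is_dist_spec(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(dist_fixed(x))
  if (is.list(x) && !is.null(x$kind)) {
    return(switch(as.character(x$kind),
      fixed   = dist_fixed(x$value),
      normal  = dist_normal(x$mean, x$sd, lower = x$lower %||% 0),
      uniform = dist_uniform(x$low, x$high),
      stop("unknown distribution kind: ", x$kind, call. = FALSE)
    ))
  }
  stop("cannot interpret value as a distribution spec", call. = FALSE)
}

#' Central value of a distribution spec
#'
#' Used for deterministic (central-parameter) runs: normal -> mean,
#' uniform -> midpoint, fixed -> value. The truncation bound is ignored for
#' the central value (all shipped normals have mean far above the bound).
#'
#' @param x A `dist_spec` or numeric scalar.
#' @return Numeric scalar.
#' @export
dist_central <- function(x) {
  x <- as_dist(x)
  switch(x$kind,
    fixed   = x$value,
    normal  = x$mean,
    uniform = (x$low + x$high) / 2
  )
}

#' Sample from a distribution spec
#'
#' Draws `n` values using the current RNG state. Normal specs are truncated
#' below at `lower` via the inverse CDF, so no draw ever falls below the
#' bound and each value consumes exactly one uniform variate.
#'
#' @param x A `dist_spec` or numeric scalar.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(x, n) {
  x <- as_dist(x)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  n <- as.integer(n)
  switch(x$kind,
    fixed = rep(x$value, n),
    normal = {
      if (x$sd == 0) {
        rep(max(x$mean, x$lower), n)
      } else {
        p0 <- stats::pnorm(x$lower, x$mean, x$sd)
        u <- stats::runif(n)
        stats::qnorm(p0 + u * (1 - p0), x$mean, x$sd)
      }
    },
    uniform = stats::runif(n, x$low, x$high)
  )
}

#' Serialize a distribution spec to a plain list (for YAML)
#' @param x A `dist_spec`.
#' @return A named list.
#' @export
dist_to_list <- function(x) {
  x <- as_dist(x)
  unclass(x)
}
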