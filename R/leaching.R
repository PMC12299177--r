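#' Reference pollutant inventory
#'
#' The six potentially toxic elements retained for assessment after
#' availability-leaching screening of the tailings (Ba, Co, Pb, Ni, As, Mn),
#' with the Class III groundwater quality limit for each, the normal
#' distribution fitted to the 100-sample availability-leachate concentrations
#' (mean and standard deviation, mg/L), the observed extremes, and the
#' detection limit used by the synthetic generator to exercise the censoring
#' path (one tenth of the Class III limit; the real analytical limits are
#' far lower for these elements).
#'
#' @return A tibble with columns `pollutant`, `class3_limit`, `mean`, `sd`,
#'   `minimum`, `maximum`, `detection_limit` (all concentrations in mg/L).
#' @export
#' @examples
#' default_pollutants()
default_pollutants <- function() {
  tibble::tibble(
    pollutant       = c("As", "Mn", "Ba", "Ni", "Co", "Pb"),
    class3_limit    = c(0.01, 0.1, 0.7, 0.02, 0.05, 0.01),
    mean            = c(0.040, 1.860, 2.600, 0.080, 0.080, 0.050),
    sd              = c(0.005, 0.600, 0.300, 0.010, 0.006, 0.010),
    minimum         = c(0.030, 0.253, 1.691, 0.057, 0.057, 0.025),
    maximum         = c(0.053, 3.325, 3.228, 0.097, 0.097, 0.091),
    detection_limit = c(0.01, 0.1, 0.7, 0.02, 0.05, 0.01) / 10
  )
}

leaching_cols <- c("sample_id", "pollutant", "concentration_mg_L", "below_detection")

#' Validate a leaching dataset
#'
#' A leaching dataset is a tibble with one row per (sample, pollutant) pair:
#' columns `sample_id`, `pollutant`, `concentration_mg_L` and
#' `below_detection`. Censored entries carry the detection limit as their
#' stored concentration with the flag set.
#'
#' @param data A data frame.
#' @return The validated data as a tibble with class `leaching_dataset`.
#' @export
as_leaching_dataset <- function(data) {
  data <- tibble::as_tibble(data)
  missing <- setdiff(leaching_cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("leaching table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tailrisk_format_error")
  }
  data$below_detection <- as.logical(data$below_detection)
  if (anyNA(data$concentration_mg_L) || anyNA(data$below_detection)) {
    abort("leaching table contains missing values", class = "tailrisk_validation_error")
  }
  if (any(data$concentration_mg_L < 0)) {
    abort("negative leaching concentration(s) found", class = "tailrisk_validation_error")
  }
  dup <- duplicated(data[, c("sample_id", "pollutant")])
  if (any(dup)) {
    abort("duplicate (sample_id, pollutant) pair(s) in leaching table",
          class = "tailrisk_validation_error")
  }
  class(data) <- c("leaching_dataset", class(data))
  data
}

#' Read a leaching-concentration table
#'
#' Reads a delimited text file of per-sample availability-leachate
#' concentrations. The file must have a header naming `sample_id`,
#' `pollutant` and `concentration_mg_L`; a logical `below_detection` column
#' is optional and defaults to `FALSE`.
#'
#' @param path Path to a CSV file.
#' @return A `leaching_dataset` tibble.
#' @export
load_leaching_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("leaching table not found: ", path), class = "tailrisk_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"below_detection" %in% names(data)) data$below_detection <- FALSE
  as_leaching_dataset(data)
}

#' Write a leaching dataset to CSV
#' @param data A `leaching_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_leaching_table <- function(data, path) {
  data <- as_leaching_dataset(data)
  readr::write_csv(data[, leaching_cols], path, progress = FALSE)
  invisible(path)
}

# statistics use detection-limit/2 for censored entries (standard
# conservative substitution); the stored value is the detection limit itself
effective_concentration <- function(data) {
  ifelse(data$below_detection, data$concentration_mg_L / 2, data$concentration_mg_L)
}

#' Summary statistics for one pollutant
#'
#' Computes mean, standard deviation, minimum and maximum of the leachate
#' concentrations for a single pollutant, substituting half the detection
#' limit for censored entries. Normality is the working assumption of the
#' downstream uncertainty model; a Shapiro-Wilk check is run and a warning
#' (never an error) is raised when it rejects at the 1% level.
#'
#' @param data A `leaching_dataset`.
#' @param pollutant Pollutant label present in `data`.
#' @param check_normality Run the Shapiro-Wilk screen (default `TRUE`).
#' @return A one-row tibble with columns `pollutant`, `n`, `mean`, `sd`,
#'   `minimum`, `maximum`, `n_censored`. The fitted normal spec is attached
#'   as attribute `"dist"` and returned by [fitted_leachate_dist()].
#' @export
summarize_pollutant <- function(data, pollutant, check_normality = TRUE) {
  data <- as_leaching_dataset(data)
  rows <- data[data$pollutant == pollutant, ]
  if (nrow(rows) == 0) {
    abort(paste0("pollutant not present in dataset: ", pollutant),
          class = "tailrisk_lookup_error")
  }
  if (nrow(rows) < 2) {
    abort(paste0("need at least 2 samples for statistics (", pollutant, ")"),
          class = "tailrisk_validation_error")
  }
  x <- effective_concentration(rows)
  if (check_normality && length(x) >= 3 && length(x) <= 5000 && stats::sd(x) > 0) {
    p <- stats::shapiro.test(x)$p.value
    if (is.finite(p) && p < 0.01) {
      warn(sprintf("%s: Shapiro-Wilk rejects normality (p = %.2g); the normal fit is retained by assumption",
                   pollutant, p))
    }
  }
  out <- tibble::tibble(
    pollutant = pollutant,
    n = length(x),
    mean = mean(x),
    sd = stats::sd(x),
    minimum = min(x),
    maximum = max(x),
    n_censored = sum(rows$below_detection)
  )
  attr(out, "dist") <- dist_normal(out$mean, out$sd)
  out
}

#' Summary statistics for every pollutant in a dataset
#'
#' @inheritParams summarize_pollutant
#' @return A tibble with one row per pollutant (see [summarize_pollutant()]).
#' @export
summarize_leaching <- function(data, check_normality = TRUE) {
  data <- as_leaching_dataset(data)
  purrr::map_dfr(sort(unique(data$pollutant)),
                 function(p) summarize_pollutant(data, p, check_normality = check_normality))
}

#' Fitted leachate-concentration distribution
#'
#' Normal distribution (truncated at zero for sampling) fitted to one
#' pollutant's leachate concentrations.
#'
#' @inheritParams summarize_pollutant
#' @return A `dist_spec`.
#' @export
fitted_leachate_dist <- function(data, pollutant) {
  s <- summarize_pollutant(data, pollutant, check_normality = FALSE)
  dist_normal(s$mean, s$sd)
}

#' Potential Hazard Index
#'
#' PHI = mean availability-leachate concentration / Class III groundwater
#' limit. PHI < 1 identifies pollutants that cannot exceed the standard at
#' the observation well (transport only dilutes), so they can be screened
#' out of the probabilistic assessment.
#'
#' @param stats A tibble with columns `pollutant` and `mean` (e.g. from
#'   [summarize_leaching()]), or a single mean concentration in mg/L.
#' @param limits A tibble with columns `pollutant` and `class3_limit`
#'   (default [default_pollutants()]), or a single positive limit in mg/L
#'   when `stats` is scalar.
#' @return A tibble with columns `pollutant`, `mean`, `class3_limit`, `phi`,
#'   `negligible` (`phi < 1`), sorted by decreasing `phi`; or a bare numeric
#'   PHI for scalar input.
#' @export
#' @examples
#' compute_phi(summarize_leaching(generate_leaching_dataset(seed = 1)))
#' compute_phi(1.86, 0.1)
compute_phi <- function(stats, limits = default_pollutants()) {
  if (is.numeric(stats) && length(stats) == 1L) {
    limit <- limits
    if (!is.numeric(limit) || length(limit) != 1L || limit <= 0) {
      abort("scalar PHI needs a single positive limit", class = "tailrisk_validation_error")
    }
    return(stats / limit)
  }
  stopifnot(is.data.frame(stats))
  limits <- tibble::as_tibble(limits)[, c("pollutant", "class3_limit")]
  if (any(limits$class3_limit <= 0)) {
    abort("class3_limit must be > 0", class = "tailrisk_validation_error")
  }
  out <- dplyr::left_join(tibble::as_tibble(stats)[, c("pollutant", "mean")],
                          limits, by = "pollutant")
  if (anyNA(out$class3_limit)) {
    abort(paste0("no Class III limit for: ",
                 paste(out$pollutant[is.na(out$class3_limit)], collapse = ", ")),
          class = "tailrisk_lookup_error")
  }
  out$phi <- out$mean / out$class3_limit
  out$negligible <- out$phi < 1
  dplyr::arrange(out, dplyr::desc(.data$phi))
}
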