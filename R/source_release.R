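#' Maximum effective release from the availability leachate
#'
#' The availability test leaches the material in two pH-controlled stages at
#' a liquid-to-solid ratio of 50 L/kg each; equal leachate volumes are mixed
#' before analysis, so a measured concentration `Cj` (mg/L) corresponds to a
#' releasable solid-phase inventory `Csw = Cj * ls_ratio_total` (mg/kg) with
#' a cumulative liquid-to-solid ratio of 100 L/kg by default.
#'
#' @param Cj Availability-leachate concentration, mg/L (>= 0).
#' @param ls_ratio_total Cumulative liquid-to-solid ratio, L/kg (> 0);
#'   default 100 (two stages of 50:1).
#' @return Maximum effective release `Csw`, mg/kg.
#' @export
#' @examples
#' availability_from_leachate(0.08) # 8 mg/kg
availability_from_leachate <- function(Cj, ls_ratio_total = 100) {
  if (any(ls_ratio_total <= 0)) {
    abort("`ls_ratio_total` must be > 0", class = "tailrisk_validation_error")
  }
  if (any(Cj < 0)) {
    abort("`Cj` must be >= 0", class = "tailrisk_validation_error")
  }
  Cj * ls_ratio_total
}

#' Source-depletion decay rate
#'
#' First-order rate at which infiltrating water depletes the releasable
#' inventory of the subgrade layer:
#' \deqn{\lambda = q C_j / (d f \rho C_{sw})}
#' with `q` the net infiltration rate (m/a), `Cj` the availability-leachate
#' concentration (mg/L), `d` the layer thickness (m), `f` the tailings
#' volume fraction, `rho` the layer density (kg/L) and `Csw` the maximum
#' effective release (mg/kg). The grouping is fixed by dimensional analysis:
#' it is the unique reading with units of 1/a. `q = alpha * P` where `alpha`
#' is the dimensionless infiltration coefficient and `P` annual
#' precipitation (m/a).
#'
#' @param q Net infiltration rate, m/a (>= 0).
#' @param Cj Availability-leachate concentration, mg/L (>= 0).
#' @param d Subgrade layer thickness, m (> 0).
#' @param f Tailings volume fraction in the layer (> 0).
#' @param rho Subgrade material density, kg/L (> 0).
#' @param Csw Maximum effective release, mg/kg (> 0 unless `Cj = 0`).
#' @return Decay rate `lambda`, 1/a.
#' @export
#' @examples
#' decay_rate(q = 0.2, Cj = 0.08, d = 0.75, f = 0.3, rho = 2, Csw = 8)
decay_rate <- function(q, Cj, d, f, rho, Csw) {
  if (any(q < 0) || any(Cj < 0)) {
    abort("`q` and `Cj` must be >= 0", class = "tailrisk_validation_error")
  }
  zero <- Cj == 0 & q >= 0
  denom <- d * f * rho * Csw
  if (any(denom <= 0 & !zero)) {
    abort("decay_rate(): d, f, rho and Csw must all be > 0",
          class = "tailrisk_validation_error")
  }
  out <- ifelse(zero, 0, q * Cj / denom)
  as.numeric(out)
}

#' Leachate concentration under source depletion
#'
#' Exponential decay of the source-strength leachate concentration,
#' `Ct = C0 * exp(-lambda * t)`.
#'
#' @param C0 Initial leachate concentration, mg/L.
#' @param lam Decay rate, 1/a (>= 0).
#' @param t Time since construction, years (>= 0); vectorised.
#' @return Concentration at `t`, mg/L.
#' @export
#' @examples
#' source_concentration(2, 4.444e-3, 2)
source_concentration <- function(C0, lam, t) {
  if (any(t < 0)) abort("`t` must be >= 0", class = "tailrisk_validation_error")
  if (any(lam < 0)) abort("`lam` must be >= 0", class = "tailrisk_validation_error")
  C0 * exp(-lam * t)
}
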