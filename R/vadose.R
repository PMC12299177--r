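#' Soil-water partition coefficient
#'
#' Volumetric-per-mass partition coefficient between bulk soil and pore
#' water in the unsaturated zone:
#' \deqn{K_{sw} = (\theta_{ws} + K_d \rho_b + H \theta_{as}) / \rho_b}
#' For the non-volatile metals considered here the conservative defaults are
#' `Kd = 0` and `H = 0` (sorption and volatilisation neglected), so
#' `Ksw = theta_ws / rho_b`.
#'
#' @param theta_ws Water-filled porosity of the unsaturated soil (0-1).
#' @param Kd Solid-water partition coefficient, L/kg (>= 0).
#' @param rho_b Soil bulk density, kg/L (> 0).
#' @param H Dimensionless Henry constant (>= 0).
#' @param theta_as Air-filled porosity (0-1).
#' @return `Ksw` in L/kg. A value of zero is degenerate (no water, no
#'   sorption) and is flagged with a warning.
#' @export
#' @examples
#' soil_water_partition(theta_ws = 0.3, rho_b = 1.5) # 0.2 L/kg
soil_water_partition <- function(theta_ws, Kd = 0, rho_b = 1.5, H = 0, theta_as = 0.2) {
  if (any(rho_b <= 0)) abort("`rho_b` must be > 0", class = "tailrisk_validation_error")
  if (any(theta_ws < 0) || any(Kd < 0) || any(H < 0) || any(theta_as < 0)) {
    abort("vadose parameters must be >= 0", class = "tailrisk_validation_error")
  }
  if (any(theta_ws + theta_as > 1 + 1e-12)) {
    abort("theta_ws + theta_as must be <= 1", class = "tailrisk_validation_error")
  }
  ksw <- (theta_ws + Kd * rho_b + H * theta_as) / rho_b
  if (any(ksw == 0)) {
    warn("soil_water_partition(): Ksw = 0 (degenerate soil parameters)")
  }
  ksw
}

#' Pore-water to groundwater dilution factor
#'
#' Dimensionless dilution of soil pore water on entry into the groundwater
#' mixing zone:
#' \deqn{LF_{spw-gw} = 1 / (1 + U_{gw} \delta_{gw} / (I W))}
#' Decreasing in the groundwater flux `Ugw * delta_gw`, increasing in the
#' infiltration flux `I * W`; always in (0, 1].
#'
#' @param Ugw Groundwater Darcy velocity, m/a (>= 0).
#' @param delta_gw Groundwater mixing-zone thickness, m (>= 0).
#' @param I Water infiltration rate into the soil, m/a (> 0).
#' @param W Road width, m (> 0).
#' @return Dimensionless factor in (0, 1].
#' @export
#' @examples
#' spw_to_gw_factor(Ugw = 25, delta_gw = 2, I = 0.3, W = 16.75)
spw_to_gw_factor <- function(Ugw, delta_gw, I, W) {
  if (any(Ugw < 0) || any(delta_gw < 0)) {
    abort("`Ugw` and `delta_gw` must be >= 0", class = "tailrisk_validation_error")
  }
  if (any(I * W <= 0)) {
    abort("`I` and `W` must be > 0 (no infiltration flux, LF undefined)",
          class = "tailrisk_validation_error")
  }
  1 / (1 + Ugw * delta_gw / (I * W))
}

#' Soil leaching and dilution factor
#'
#' Converts releasable solid-phase content (mg/kg) into the groundwater
#' concentration entering the saturated zone (mg/L):
#' `LF = LFspw_gw / Ksw`, in kg/L.
#'
#' @param LFspw_gw Pore-water to groundwater dilution factor
#'   (see [spw_to_gw_factor()]).
#' @param Ksw Soil-water partition coefficient, L/kg (> 0).
#' @return `LF` in kg/L.
#' @export
#' @examples
#' leaching_factor(0.0913, 0.2)
leaching_factor <- function(LFspw_gw, Ksw) {
  if (any(Ksw <= 0)) {
    abort("`Ksw` must be > 0: degenerate soil parameters (theta_ws = Kd = H = 0?)",
          class = "tailrisk_validation_error")
  }
  LFspw_gw / Ksw
}
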