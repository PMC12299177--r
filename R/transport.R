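# complementary error function via the exact pnorm relation;
# log_erfc uses pnorm's log tail so exp(ux/DL) * erfc(b) never overflows
erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)
log_erfc <- function(x) log(2) + stats::pnorm(-sqrt(2) * x, log.p = TRUE)

#' Darcy seepage velocity
#'
#' `u = K * i / n`: hydraulic conductivity times hydraulic gradient over
#' effective porosity.
#'
#' @param K Hydraulic conductivity, m/d (>= 0).
#' @param i Hydraulic gradient, dimensionless (>= 0).
#' @param n Effective porosity, in (0, 1).
#' @return Seepage velocity, m/d.
#' @export
#' @examples
#' seepage_velocity(30, 0.0045, 0.4)
seepage_velocity <- function(K, i, n) {
  if (any(n <= 0) || any(n >= 1)) {
    abort("porosity `n` must be in (0, 1)", class = "tailrisk_validation_error")
  }
  if (any(K < 0) || any(i < 0)) {
    abort("`K` and `i` must be >= 0", class = "tailrisk_validation_error")
  }
  K * i / n
}

#' Dilution-attenuation factor (analytical)
#'
#' Relative breakthrough concentration at distance `x` for a continuous
#' unit-concentration source in one-dimensional advection-dispersion
#' (no retardation or decay):
#' \deqn{DAF(t) = \tfrac12 \mathrm{erfc}\!\left(\frac{x-ut}{2\sqrt{D_L t}}\right)
#'   + \tfrac12 e^{ux/D_L}\, \mathrm{erfc}\!\left(\frac{x+ut}{2\sqrt{D_L t}}\right)}
#' The second term is evaluated as `exp(ux/DL + log(erfc(b)))` so it never
#' overflows, even for `ux/DL` in the hundreds. `DAF` lies in `[0, 1]`, is
#' non-decreasing in `t`, and tends to 1 as `t` grows. `t <= 0` returns 0
#' (pre-breakthrough convention).
#'
#' @param x Distance from source to observation well, m (> 0).
#' @param u Seepage velocity, m/d (>= 0).
#' @param DL Longitudinal dispersion coefficient, m^2/d (> 0).
#' @param t Time, days; vectorised.
#' @return Dimensionless DAF, same length as `t`.
#' @export
#' @examples
#' dilution_attenuation_factor(100, 0.1, 5, 1000)
dilution_attenuation_factor <- function(x, u, DL, t) {
  if (any(DL <= 0)) abort("`DL` must be > 0", class = "tailrisk_validation_error")
  if (any(x <= 0)) abort("`x` must be > 0", class = "tailrisk_validation_error")
  if (any(u < 0)) abort("`u` must be >= 0", class = "tailrisk_validation_error")
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    tp <- t[pos]
    s <- 2 * sqrt(DL * tp)
    a <- (x - u * tp) / s
    b <- (x + u * tp) / s
    daf <- 0.5 * erfc(a) + 0.5 * exp(u * x / DL + log_erfc(b))
    out[pos] <- pmin(pmax(daf, 0), 1)
  }
  out
}

# vectorised over draws (rows) and times (columns); x/u/DL vectors of length
# n_draw (scalars recycle), t_d vector of times in days.
# Returns an n_draw x n_time matrix.
daf_matrix <- function(x, u, DL, t_d) {
  s <- 2 * sqrt(outer(DL, t_d))
  ut <- outer(u, t_d)
  a <- (x - ut) / s
  b <- (x + ut) / s
  daf <- 0.5 * erfc(a) + 0.5 * exp((u * x / DL) + log_erfc(b))
  daf[, t_d <= 0] <- 0
  pmin(pmax(daf, 0), 1)
}

#' Dilution-attenuation factor (finite-difference oracle)
#'
#' Independent numerical solution of the one-dimensional advection-
#' dispersion equation \eqn{\partial C/\partial t = D_L \partial^2 C/\partial x^2
#' - u\, \partial C/\partial x} with a continuous unit-concentration inlet,
#' used to verify [dilution_attenuation_factor()]. Crank-Nicolson time
#' stepping with central spatial differences on a domain long enough that
#' the far (zero-concentration) boundary stays inert; retardation `R`
#' rescales the time derivative and `gamma` adds first-order decay.
#'
#' The grid must satisfy a cell Peclet number `u*dx/DL <= 2` and a Courant
#' number `u*dt/dx <= 1`; violations raise a configuration error.
#'
#' @param x Observation distance, m (> 0).
#' @param u Seepage velocity, m/d (>= 0).
#' @param DL Longitudinal dispersion coefficient, m^2/d (> 0).
#' @param t Output times, days (> 0); may be a vector.
#' @param dx Cell size, m.
#' @param dt Time step, d. Default keeps the Courant number at or below 0.8
#'   and uses at least 200 steps to the last output time.
#' @param L Domain length, m. Default extends past the advective front plus
#'   six dispersive standard deviations (at least `2x`).
#' @param R Retardation factor (>= 1), default 1.
#' @param gamma First-order decay rate, 1/d (>= 0), default 0.
#' @return Numeric vector of DAF values at `t`.
#' @export
#' @examples
#' daf_numerical_oracle(100, 0.1, 5, 1000)
daf_numerical_oracle <- function(x, u, DL, t, dx = 1,
                                 dt = NULL, L = NULL, R = 1, gamma = 0) {
  stopifnot(length(x) == 1L, length(u) == 1L, length(DL) == 1L)
  if (any(t <= 0)) abort("oracle output times must be > 0", class = "tailrisk_validation_error")
  if (DL <= 0 || x <= 0 || u < 0 || R < 1 || gamma < 0) {
    abort("invalid transport parameters", class = "tailrisk_validation_error")
  }
  t_max <- max(t)
  if (is.null(L)) L <- max(2 * x, x + u * t_max / R + 6 * sqrt(2 * DL * t_max / R))
  if (is.null(dt)) dt <- min(if (u > 0) 0.8 * dx / u else Inf, t_max / 200)
  if (u * dx / DL > 2 + 1e-12) {
    abort(sprintf("grid Peclet number %.3g > 2: reduce dx", u * dx / DL),
          class = "tailrisk_config_error")
  }
  if (u * dt / dx > 1 + 1e-12) {
    abort(sprintf("Courant number %.3g > 1: reduce dt", u * dt / dx),
          class = "tailrisk_config_error")
  }

  nx <- ceiling(L / dx)
  xg <- seq(0, by = dx, length.out = nx + 1)
  ni <- nx - 1  # interior nodes; C[0] = 1 (inlet), C[nx] = 0 (far boundary)

  # spatial operator on interior nodes: (1/R)(DL D2 - u D1) - gamma
  ad <- DL / dx^2 / R
  av <- u / (2 * dx) / R
  lower <- ad + av     # coefficient of C[i-1]
  diag0 <- -2 * ad - gamma
  upper <- ad - av     # coefficient of C[i+1]

  tri <- function(dl, d0, du) {
    Matrix::bandSparse(ni, ni, k = -1:1,
                       diagonals = list(rep(dl, ni - 1), rep(d0, ni), rep(du, ni - 1)))
  }

  Lop <- tri(lower, diag0, upper)
  Id <- Matrix::Diagonal(ni)
  A_dt <- Id - (dt / 2) * Lop
  B_dt <- Id + (dt / 2) * Lop

  C <- numeric(ni)
  times <- sort(unique(t))
  out <- numeric(length(times))
  t_now <- 0
  for (j in seq_along(times)) {
    tt <- times[j]
    while (t_now < tt - 1e-9) {
      step <- min(dt, tt - t_now)
      if (abs(step - dt) < 1e-12) {
        A <- A_dt; B <- B_dt
      } else {
        A <- Id - (step / 2) * Lop
        B <- Id + (step / 2) * Lop
      }
      rhs <- as.numeric(B %*% C)
      rhs[1] <- rhs[1] + step * lower  # Dirichlet inlet C0 = 1 on both levels
      C <- as.numeric(Matrix::solve(A, rhs))
      t_now <- t_now + step
    }
    out[j] <- stats::approx(xg, c(1, C, 0), xout = x)$y
  }
  out[match(t, times)]
}
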