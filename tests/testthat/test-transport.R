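test_that("seepage velocity is Darcy flux over porosity", {
  expect_equal(seepage_velocity(30, 0, 0.4), 0)
  expect_equal(seepage_velocity(30, 0.0045, 0.4), 0.3375)
  expect_equal(seepage_velocity(10, 0.003, 0.5), 0.06)
  expect_error(seepage_velocity(30, 0.0045, 0), class = "tailrisk_validation_error")
})

test_that("analytic DAF matches an independent reference implementation", {
  # reference values from scipy.special.erfc/erfcx (double precision)
  expect_equal(dilution_attenuation_factor(100, 0.1, 5, 1000),
               0.6681020012231708, tolerance = 1e-12)
  expect_equal(dilution_attenuation_factor(100, 0.3375, 7.5, 500),
               0.8725082452641266, tolerance = 1e-12)
  expect_equal(dilution_attenuation_factor(100, 0.06, 5, 18250),
               0.9986286102330831, tolerance = 1e-12)
})

test_that("DAF limits, bounds and overflow safety hold", {
  expect_equal(dilution_attenuation_factor(100, 0.1, 5, 1e9), 1, tolerance = 1e-6)
  expect_lt(dilution_attenuation_factor(100, 0.1, 5, 1), 1e-12) # pre-breakthrough
  expect_equal(dilution_attenuation_factor(100, 0.1, 5, c(-5, 0)), c(0, 0))

  # ux/DL = 700 and 2000: the scaled-erfc path must stay finite and bounded
  expect_equal(dilution_attenuation_factor(100, 7, 1, 50), 1, tolerance = 1e-9)
  v <- dilution_attenuation_factor(100, 20, 1, 3)
  expect_true(is.finite(v))
  expect_equal(v, 3.780889448298297e-60, tolerance = 1e-6)

  # bounded in [0,1] and non-decreasing in t across a parameter lattice
  tt <- c(1, 10, 50, 100, 300, 1000, 5000, 2e4, 1e5)
  for (u in c(0, 0.05, 0.34, 1, 5)) {
    for (DL in c(5, 7.5, 10)) {
      daf <- dilution_attenuation_factor(100, u, DL, tt)
      expect_true(all(daf >= 0 & daf <= 1 & is.finite(daf)))
      expect_true(all(diff(daf) >= -1e-12))
    }
  }

  # at the advective breakthrough time the first term alone contributes 1/4,
  # and the total is at least 1/2 of the eventual plateau
  daf_bt <- dilution_attenuation_factor(100, 0.3375, 7.5, 100 / 0.3375)
  expect_gte(daf_bt, 0.25)
  expect_error(dilution_attenuation_factor(100, 0.1, 0, 10),
               class = "tailrisk_validation_error")
})

test_that("finite-difference oracle reproduces pure diffusion", {
  # u = 0: closed form C(x,t)/C0 = erfc(x / (2 sqrt(DL t)))
  got <- daf_numerical_oracle(100, 0, 5, 1000, dx = 1)
  expect_equal(got, 0.31731050786291415, tolerance = 1e-3)
})

test_that("finite-difference oracle agrees with the analytic solution", {
  got <- daf_numerical_oracle(100, 0.1, 5, 1000, dx = 1)
  expect_equal(got, dilution_attenuation_factor(100, 0.1, 5, 1000),
               tolerance = 5e-3)
})

test_that("oracle discrepancy shrinks when the grid is refined", {
  exact <- dilution_attenuation_factor(100, 0.3375, 7.5, 500)
  err <- function(dx) abs(daf_numerical_oracle(100, 0.3375, 7.5, 500, dx = dx) - exact)
  e2 <- err(2)
  e1 <- err(1)
  expect_lt(e1, e2) # at least first-order spatial convergence
})

test_that("unstable grids are rejected", {
  expect_error(daf_numerical_oracle(100, 5, 1, 100, dx = 1),
               class = "tailrisk_config_error")  # cell Peclet > 2
  expect_error(daf_numerical_oracle(100, 0.5, 5, 100, dx = 1, dt = 10),
               class = "tailrisk_config_error")  # Courant > 1
  expect_error(daf_numerical_oracle(100, 0.1, 5, -1),
               class = "tailrisk_validation_error")
})
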