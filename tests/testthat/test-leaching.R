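test_that("leaching tables parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,pollutant,concentration_mg_L,below_detection",
               "S1,Ni,0.08,FALSE", "S2,Ni,0.09,FALSE", "S3,Ni,0.07,FALSE"),
             path)
  d <- load_leaching_table(path)
  expect_s3_class(d, "leaching_dataset")
  expect_equal(sum(d$pollutant == "Ni"), 3)

  writeLines(c("sample_id,pollutant,concentration_mg_L,below_detection",
               "S1,Ni,-0.01,FALSE"), path)
  expect_error(load_leaching_table(path), class = "tailrisk_validation_error")

  writeLines(c("sample_id,concentration_mg_L", "S1,0.08"), path)
  expect_error(load_leaching_table(path), class = "tailrisk_format_error")

  # synthetic campaign-size dataset round-trips losslessly
  gen <- generate_leaching_dataset(n_samples = 100, seed = 11)
  write_leaching_table(gen, path)
  back <- load_leaching_table(path)
  expect_equal(as.data.frame(back), as.data.frame(gen))
})

test_that("duplicate sample/pollutant pairs are rejected", {
  d <- tiny_leaching()
  expect_error(as_leaching_dataset(rbind(d, d[1, ])),
               class = "tailrisk_validation_error")
})

test_that("summary statistics are exact, order-invariant and bounded", {
  d <- as_leaching_dataset(tibble::tibble(
    sample_id = c("a", "b", "c"), pollutant = "Ni",
    concentration_mg_L = c(0.06, 0.08, 0.10), below_detection = FALSE
  ))
  s <- summarize_pollutant(d, "Ni")
  expect_equal(s$mean, 0.08)
  expect_equal(s$minimum, 0.06)
  expect_equal(s$maximum, 0.10)
  expect_equal(s$n, 3)

  # permutation invariance
  s2 <- summarize_pollutant(d[c(3, 1, 2), ], "Ni")
  expect_equal(s2, s)

  expect_error(summarize_pollutant(d, "Hg"), class = "tailrisk_lookup_error")
  expect_error(summarize_pollutant(d[1, ], "Ni"), class = "tailrisk_validation_error")

  # min <= mean <= max on arbitrary generated data
  gen <- generate_leaching_dataset(n_samples = 50, seed = 3)
  st <- summarize_leaching(gen)
  expect_true(all(st$minimum <= st$mean & st$mean <= st$maximum))
  expect_true(all(st$sd >= 0))
})

test_that("censored values enter statistics at half the detection limit", {
  d <- as_leaching_dataset(tibble::tibble(
    sample_id = c("a", "b", "c", "d"), pollutant = "Pb",
    concentration_mg_L = c(0.02, 0.04, 0.001, 0.001),
    below_detection = c(FALSE, FALSE, TRUE, TRUE)
  ))
  s <- summarize_pollutant(d, "Pb", check_normality = FALSE)
  expect_equal(s$mean, mean(c(0.02, 0.04, 0.0005, 0.0005)))
  expect_equal(s$n_censored, 2)
})

test_that("large synthetic sample reproduces the Mn generating statistics", {
  poll <- default_pollutants()[default_pollutants()$pollutant == "Mn", ]
  gen <- generate_leaching_dataset(poll, n_samples = 20000, seed = 5)
  s <- summarize_pollutant(gen, "Mn", check_normality = FALSE)
  # agreement with the generating parameters within Monte Carlo error
  expect_equal(s$mean, 1.860, tolerance = 3 * 0.600 / sqrt(20000) / 1.860)
  expect_equal(s$sd, 0.600, tolerance = 0.02)
})

test_that("PHI is mean over limit, with scale invariance and screening flag", {
  expect_equal(compute_phi(0.1, 0.1), 1)           # mean = limit
  expect_equal(compute_phi(1.860, 0.1), 18.6)      # Mn from the fitted mean
  expect_equal(compute_phi(2.600, 0.7), 3.714286, tolerance = 1e-6) # Ba
  expect_equal(compute_phi(2 * 1.860, 2 * 0.1), 18.6) # scaling both is neutral
  expect_error(compute_phi(1, 0), class = "tailrisk_validation_error")

  stats <- default_pollutants()[, c("pollutant", "mean")]
  phi <- compute_phi(stats)
  expect_equal(phi$pollutant[1], "Mn") # highest hazard index first
  expect_true(phi$negligible[phi$pollutant == "Co"] ||
              phi$phi[phi$pollutant == "Co"] >= 1) # flag consistent with phi
  expect_equal(phi$negligible, phi$phi < 1)
  expect_error(compute_phi(tibble::tibble(pollutant = "Zn", mean = 1)),
               class = "tailrisk_lookup_error")
})
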