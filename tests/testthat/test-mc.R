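test_that("parameter draws respect supports, seeds and prefix stability", {
  sc <- coarse_scenario()
  d <- sample_parameters(sc, "Mn", n_iter = 500, seed = 11)
  expect_equal(nrow(d), 500)
  expect_true(all(d$W >= 3.5 & d$W <= 30))         # road width U(3.5, 30)
  expect_true(all(d$d >= 0.3 & d$d <= 1.2))
  expect_true(all(d$alpha >= 0))                   # truncated normal
  expect_true(all(d$cj >= 0))
  expect_true(all(d$I == 0.3))                     # fixed parameter replicated
  expect_equal(d$precip, d$precip_mm_a / 1000)

  d2 <- sample_parameters(sc, "Mn", n_iter = 500, seed = 11)
  expect_identical(d, d2)                          # same seed, same matrix

  d3 <- sample_parameters(sc, "Mn", n_iter = 1000, seed = 11)
  expect_equal(d3[1:500, ], d, ignore_attr = TRUE) # prefix stability
})

test_that("degenerate Monte Carlo equals a deterministic run", {
  sc <- all_fixed_scenario(coarse_scenario())
  spec <- default_pollutants()
  cj0 <- spec$mean[spec$pollutant == "Ni"]
  res <- run_monte_carlo(sc, "Ni", n_iter = 1, seed = 1,
                         cj_dist = dist_fixed(cj0))
  pk <- peak_exposure(exposure_timeseries(sc, "Ni"))
  expect_equal(res$peaks$peak_mg_L, pk$peak_mg_L, tolerance = 1e-12)
  expect_equal(res$peaks$peak_time_a, pk$peak_time_a)
})

test_that("summaries obey quantile ordering and exceedance monotonicity", {
  sc <- coarse_scenario()
  res <- run_monte_carlo(sc, "Mn", n_iter = 400, seed = 21)
  s <- summarize_mc(res)
  expect_true(s$p50 <= s$p95 && s$p95 <= s$p99)
  expect_true(all(res$peaks$peak_mg_L >= 0))
  expect_equal(s$exceed_multiple, s$p95 / 0.1)

  # exceedance probability is non-increasing in the limit value
  probs <- vapply(c(0.001, 0.01, 0.05, 0.1, 1),
                  function(L) mean(res$peaks$peak_mg_L > L), numeric(1))
  expect_true(all(diff(probs) <= 0))

  # bit-identical summaries for a fixed (seed, config)
  s2 <- summarize_mc(run_monte_carlo(sc, "Mn", n_iter = 400, seed = 21))
  expect_identical(s, s2)
})

test_that("hand-built peak sets give exact empirical summaries", {
  res <- structure(list(
    peaks = tibble::tibble(iter = 1:100, peak_mg_L = as.numeric(1:100),
                           peak_time_a = 1),
    pollutant = "synthetic", class3_limit = 90, n_iter = 100L, seed = 0L
  ), class = "mc_result")
  s <- summarize_mc(res)
  expect_equal(s$exceed_prob, 0.10)           # brute-force count: 91..100
  expect_equal(s$p50, 50.5)                   # linear-interpolation quantile

  const <- res
  const$peaks$peak_mg_L <- rep(2, 100)
  sc <- summarize_mc(const)
  expect_equal(sc$p50, sc$p95)
  expect_equal(sc$p95, sc$p99)
  expect_true(sc$exceed_prob %in% c(0, 1))
})

test_that("tidy and glance expose the CDF and the risk summary", {
  res <- run_monte_carlo(coarse_scenario(), "Ni", n_iter = 200, seed = 2)
  cdf <- tidy(res)
  expect_equal(nrow(cdf), 200)
  expect_true(!is.unsorted(cdf$conc_mg_L))
  expect_equal(cdf$cum_freq[200], 1)
  g <- glance(res)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n_iter, 200)
})
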