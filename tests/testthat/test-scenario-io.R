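test_that("defaults fill a minimal configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("pollutants:\n- pollutant: Mn\n  class3_limit: 0.1\n  mean: 1.86\n  sd: 0.6", path)
  sc <- load_scenario(path)
  expect_equal(sc$pollutants$pollutant, "Mn")
  expect_equal(sc$vadose$I, dist_fixed(0.3))           # defaults filled
  expect_equal(sc$source$alpha, dist_normal(0.2, 0.05))
  expect_equal(sc$transport$x, dist_fixed(100))
  expect_equal(dist_central(sc$precip_mm_a), 900)
})

test_that("invalid configurations are rejected with informative classes", {
  expect_error(scenario_config(source = list(d = -1)),
               class = "tailrisk_validation_error")
  expect_error(scenario_config(source = list(unknown_param = 1)),
               class = "tailrisk_schema_error")
  expect_error(scenario_config(transport = list(n = dist_fixed(1.5))),
               class = "tailrisk_validation_error")

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_key: 1", path)
  expect_error(load_scenario(path), class = "tailrisk_schema_error")

  writeLines("vadose:\n  W:\n    value: 10\n    unit: km", path)
  err <- tryCatch(load_scenario(path), error = function(e) conditionMessage(e))
  expect_match(err, "W")
  expect_match(err, "m")
})

test_that("scenarios round-trip through YAML", {
  sc <- scenario_config(
    precip_mm_a = dist_uniform(400, 800),
    source = list(f = dist_fixed(0.42)),
    transport = list(DL = dist_normal(7, 0.5)),
    couple_infiltration = TRUE,
    horizon_a = 25, dt_a = 0.1, n_iter = 123
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- load_scenario(path)
  expect_equal(back$precip_mm_a, sc$precip_mm_a)
  expect_equal(back$source, sc$source)
  expect_equal(back$vadose, sc$vadose)
  expect_equal(back$transport, sc$transport)
  expect_equal(back$couple_infiltration, TRUE)
  expect_equal(back$n_iter, sc$n_iter)
  expect_equal(as.data.frame(back$pollutants), as.data.frame(sc$pollutants))
})

test_that("fix_parameter pins values and validates groups", {
  sc <- fix_parameter(default_scenario(), "source", "f", 0.6)
  expect_equal(sc$source$f, dist_fixed(0.6))
  sc <- fix_parameter(sc, "precip", value = 500)
  expect_equal(sc$precip_mm_a, dist_fixed(500))
  expect_error(fix_parameter(sc, "source", "nope", 1),
               class = "tailrisk_schema_error")
  expect_error(fix_parameter(sc, "weather", "P", 1),
               class = "tailrisk_schema_error")
})

test_that("the command-line surface is deterministic end to end", {
  dir <- withr::local_tempdir()
  expect_equal(suppressMessages(tailrisk_cli(c("synth", "--out", dir, "--seed", "4"))), 0L)
  cfg <- file.path(dir, "scenario.yaml")
  expect_true(file.exists(cfg) && file.exists(file.path(dir, "leaching.csv")))

  out1 <- file.path(dir, "mc1"); out2 <- file.path(dir, "mc2")
  for (o in c(out1, out2)) {
    st <- suppressMessages(tailrisk_cli(c("mc", "--config", cfg, "--seed", "42",
                                          "--n-iter", "150", "--pollutant", "Mn",
                                          "--out", o)))
    expect_equal(st, 0L)
  }
  expect_identical(readLines(file.path(out1, "mc_summary.json")),
                   readLines(file.path(out2, "mc_summary.json")))

  # phi writes a six-row table with provenance header
  st <- suppressMessages(tailrisk_cli(c("phi", "--config", cfg,
                                        "--leaching", file.path(dir, "leaching.csv"),
                                        "--out", dir)))
  expect_equal(st, 0L)
  phi <- readr::read_csv(file.path(dir, "phi.csv"), comment = "#",
                         show_col_types = FALSE)
  expect_equal(nrow(phi), 6)
  expect_match(readLines(file.path(dir, "phi.csv"), n = 1), "config_hash")

  # blend sweep CSV has a monotone ratio column
  st <- suppressMessages(tailrisk_cli(c("blend-sweep", "--config", cfg,
                                        "--regime", "semi_humid", "--pollutant", "Mn",
                                        "--f-grid", "0.2,0.6,1.0",
                                        "--n-iter", "100", "--seed", "2",
                                        "--out", dir)))
  expect_equal(st, 0L)
  bs <- readr::read_csv(file.path(dir, "blend_sweep.csv"), comment = "#",
                        show_col_types = FALSE)
  expect_true(all(diff(bs$ratio_to_standard) >= 0))

  expect_equal(suppressMessages(tailrisk_cli("frobnicate")), 2L)
  expect_equal(suppressMessages(tailrisk_cli(character(0))), 2L)
  expect_equal(suppressMessages(tailrisk_cli(c("region", "--pollutant", "Ni"))), 1L)
})
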