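# coarse-grid scenario for fast Monte Carlo tests (the physics is smooth in
# time, so a 0.5 a grid still resolves the peak to a few percent)
coarse_scenario <- function(...) {
  scenario_config(horizon_a = 30, dt_a = 0.5, ...)
}

# scenario with every parameter pinned at its central value (degenerate MC)
all_fixed_scenario <- function(base = default_scenario()) {
  for (g in c("source", "vadose", "transport")) {
    for (f in names(base[[g]])) {
      base[[g]][[f]] <- dist_fixed(dist_central(base[[g]][[f]]))
    }
  }
  base$precip_mm_a <- dist_fixed(dist_central(base$precip_mm_a))
  base
}

# tiny three-sample leaching table used across leaching tests
tiny_leaching <- function() {
  as_leaching_dataset(tibble::tibble(
    sample_id = c("S1", "S2", "S3"),
    pollutant = "Ni",
    concentration_mg_L = c(0.08, 0.09, 0.07),
    below_detection = FALSE
  ))
}
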