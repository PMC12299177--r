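Package: tailrisk
Title: Probabilistic Groundwater Risk Assessment for Iron Tailings in Road Subgrade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Probabilistic environmental-risk pipeline for beneficial reuse of
    iron tailings as road subgrade material. Couples an exponential
    source-depletion model of leachate release with a vadose-zone leaching and
    dilution factor and a one-dimensional advection-dispersion
    dilution-attenuation factor at a downgradient observation well, and
    propagates parameter uncertainty by Monte Carlo simulation to obtain
    cumulative frequency curves, percentile exposure concentrations, and
    probabilities of exceeding Class III groundwater quality limits. Includes
    dry-wet regional climate scenarios, blend-ratio (tailings mixing fraction)
    management sweeps, a synthetic leaching-data generator emulating
    availability-test results, and a finite-difference transport oracle for
    verifying the analytical solution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
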