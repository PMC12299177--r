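# tailrisk

Probabilistic groundwater risk assessment for iron tailings reused in road
subgrade. For environmental engineers and risk assessors deciding whether —
and at what blending ratio — mine tailings can be placed in a road's cushion
layer without pushing heavy-metal concentrations in shallow groundwater past
Class III quality limits at a downgradient well.

## The model

Rainfall infiltration (`q = αP`) leaches a releasable inventory
`Csw = 100·Cj` (mg/kg, from a two-stage availability test at a cumulative
liquid-to-solid ratio of 100 L/kg) out of the subgrade at a first-order rate

    λ = q·Cj / (d·f·ρ·Csw),      Ct = C0·e^(−λt)

The leachate is diluted through the vadose zone,

    LFspw−gw = 1 / (1 + Ugw·δgw / (I·W)),      Ksw = (θws + Kd·ρb + H·θas) / ρb

and attenuated along the saturated flow path to the well at x = 100 m by the
one-dimensional advection–dispersion breakthrough solution

    DAF(t) = ½·erfc[(x − ut) / (2√(DL·t))] + ½·e^(ux/DL)·erfc[(x + ut) / (2√(DL·t))]

The well concentration is `cgw(t) = cw(t) × LF × DAF(t)`. Uncertain
parameters (infiltration coefficient, layer geometry, tailings fraction,
road width, hydraulics, and the per-pollutant leachate concentration) carry
the standard distributions of the assessment inventory and are propagated by
Monte Carlo simulation; the per-draw risk metric is the temporal peak of
`cgw`, summarised as an exceedance probability and a 95th-percentile
"exposure concentration". Regional scenarios couple infiltration to the
precipitation band of four dry–wet climate regimes, and a blend-ratio sweep
inverts the risk into the maximum admissible tailings volume fraction
`f_max`. A Crank–Nicolson finite-difference solver ships as an independent
oracle for the analytic transport solution. See the methods vignette
(`vignettes/tailings-road-risk.Rmd`) for assumptions and numerical choices.

## Worked example

```r
library(tailrisk)

# 1. Screen pollutants with the Potential Hazard Index (mean leachate / limit)
data <- generate_leaching_dataset(n_samples = 100, seed = 7)  # or load_leaching_table()
compute_phi(summarize_leaching(data))
#>   pollutant   mean class3_limit   phi negligible
#> 1 Mn        1.84           0.1  18.4  FALSE
#> 2 Pb        0.0498         0.01  4.98 FALSE
#> 3 As        0.0403         0.01  4.03 FALSE
#> 4 Ni        0.0795         0.02  3.97 FALSE
#> 5 Ba        2.58           0.7   3.69 FALSE
#> 6 Co        0.0802         0.05  1.60 FALSE

# 2. Monte Carlo risk at the base-case site (humid, 900 mm/a)
sc <- default_scenario()
res <- run_monte_carlo(sc, "Mn", n_iter = 10000, seed = 7)
res
#> <mc_result> Mn: 10000 iterations (seed 7)
#>   peak concentration p50/p95/p99: 0.04012 / 0.1208 / 0.157 mg/L
#>   P(peak > 0.1 mg/L) = 0.098; p95/limit = 1.21
autoplot(res)       # cumulative frequency curve
glance(res)         # one-row risk summary; tidy(res) gives the CDF

# 3. Management limit: how much tailings can a semi-humid region accept?
bs <- blend_sweep(sc, "semi_humid", "Mn", f_grid = seq(0.2, 1, 0.2),
                  n_iter = 2000, seed = 7)
bs
#>     f exposure_conc_mg_L ratio_to_standard exceed_prob
#> 1 0.2             0.0319             0.319      0.0000
#> 2 0.4             0.0648             0.648      0.0030
#> 3 0.6             0.0978             0.978      0.0435
#> 4 0.8             0.1305             1.305      0.1455
#> 5 1.0             0.1635             1.635      0.2425
attr(bs, "f_max")
#> [1] 0.6
```

Reading the output: manganese is the dominant hazard (PHI ≈ 18); at the
base-case site its peak well concentration exceeds the 0.1 mg/L limit in
about 10% of parameter draws and the 95th-percentile peak is about 1.2× the
limit. In a semi-humid climate the 95th-percentile exposure stays at or
below the standard up to a 60% tailings volume fraction, which is the
recommended mixing cap there.

A command-line surface wraps the same functions:

```sh
exec/tailrisk synth --out fixture --seed 1
exec/tailrisk mc --config fixture/scenario.yaml --pollutant Mn --seed 1 --out results
exec/tailrisk blend-sweep --config fixture/scenario.yaml --regime semi_humid \
    --pollutant Mn --seed 1 --out results
```

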