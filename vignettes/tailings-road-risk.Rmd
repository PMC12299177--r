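---
title: "Probabilistic groundwater risk from iron tailings in road subgrade: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic groundwater risk from iron tailings in road subgrade: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailrisk)
```

## The problem

Iron-ore beneficiation leaves large volumes of fine tailings. A common
beneficial-reuse route blends them into road subgrade cushion material. The
environmental question is whether rainfall percolating through the subgrade
can leach enough of the potentially toxic metals (As, Mn, Ba, Ni, Co, Pb)
into shallow groundwater to exceed Class III groundwater quality limits at a
downgradient receptor, and — since the answer depends on uncertain site
parameters — with what probability. `tailrisk` implements that assessment
as a chain of three factors, propagates parameter uncertainty by Monte
Carlo simulation, and inverts the result into a management limit on the
tailings mixing ratio per climate region.

## Model chain

**Source depletion.** The releasable inventory of a pollutant is estimated
from a two-stage availability leaching test: a measured availability-leachate
concentration $C_j$ (mg/L) at a cumulative liquid-to-solid ratio of
$100$ L/kg implies a maximum effective release
$C_{sw} = 100\, C_j$ (mg/kg). Infiltrating water ($q = \alpha P$, with
$\alpha$ the dimensionless infiltration coefficient and $P$ annual
precipitation in m/a) washes this inventory out at a first-order rate

$$\lambda = \frac{q\, C_j}{d\, f\, \rho\, C_{sw}}, \qquad
  C_t = C_0\, e^{-\lambda t},$$

where $d$ is the layer thickness (m), $f$ the tailings volume fraction,
$\rho$ the layer density (kg/L). This grouping of the symbols is the unique
one with units of $a^{-1}$, and it is exactly mass-conserving: the
infinite-horizon leached mass per unit footprint area,
$\int_0^\infty q\, C_0 e^{-\lambda t}\,dt = q C_0/\lambda$, equals the
available inventory $d f \rho C_{sw}$ when $C_0 = C_j$ (the test suite
asserts this to a relative error below $10^{-9}$).

**Vadose-zone leaching factor.** Pore water leaving the subgrade is diluted
on entry into the groundwater mixing zone,

$$LF_{spw\text{-}gw} = \frac{1}{1 + U_{gw}\delta_{gw}/(I\,W)} \in (0,1],
\qquad
K_{sw} = \frac{\theta_{ws} + K_d\rho_b + H\,\theta_{as}}{\rho_b},
\qquad
LF = \frac{LF_{spw\text{-}gw}}{K_{sw}} \; \text{(kg/L)},$$

with $U_{gw}$ the groundwater Darcy velocity (m/a), $\delta_{gw}$ the
mixing-zone thickness (m), $I$ the infiltration rate (m/a), $W$ the road
width (m). For the six non-volatile metals the conservative defaults are
$K_d = 0$ and $H = 0$ (sorption and volatilisation neglected), so
$K_{sw} = \theta_{ws}/\rho_b = 0.2$ L/kg. These groupings are again fixed by
dimensional analysis ($LF$ in kg/L, $LF_{spw\text{-}gw}$ dimensionless).

**Saturated transport.** Along the flow path to the observation well at
$x = 100$ m, a continuous source is attenuated by one-dimensional
advection–dispersion. With seepage velocity $u = K i / n$ (m/d) and
longitudinal dispersion $D_L$ (m²/d), the dilution–attenuation factor is

$$DAF(t) = \tfrac12\,\mathrm{erfc}\!\left(\frac{x - ut}{2\sqrt{D_L t}}\right)
 + \tfrac12\, e^{u x / D_L}\,
   \mathrm{erfc}\!\left(\frac{x + ut}{2\sqrt{D_L t}}\right),$$

which lies in $[0,1]$, is non-decreasing in $t$, and tends to 1. Retardation
and first-order decay are fixed at $R = 1$, $\gamma = 0$: the analytic
solution used for assessment contains neither, and dropping them is the
conservative choice for metals. (The finite-difference oracle accepts both
for verification purposes.)

**Coupling.** The well concentration is
$c_{gw}(t) = c_w(t) \times LF \times DAF(t)$, with $c_w$ the released
solid-phase content in mg/kg. Two readings of $c_w$ are implemented:

* `cw_mode = "equilibrium"` (default): $c_w = K_{sw} C_t$, the soil content
  in local equilibrium with the pore-water leachate, so
  $c_{gw} = C_t \cdot LF_{spw\text{-}gw} \cdot DAF$. This keeps the product
  dimensionally exact and treats the subgrade pore water as the leachate
  itself; it reproduces the magnitude of the published base-case exceedance
  probabilities and blend-sweep concentrations.
* `cw_mode = "inventory"`: $c_w = f\,C_{sw} e^{-\lambda t}$, the full
  releasable inventory. This larger, screening-style reading multiplies the
  default by $100 f / K_{sw}$ and is retained for sensitivity analysis.

Similarly the initial leachate concentration defaults to $C_0 = f C_j$
(`c0_mode = "f_cj"`): the blend fraction scales the pore-water concentration,
which is what makes the blend-ratio sweep meaningful; $C_0 = C_j$ is
available as the alternative.

The per-realisation **risk metric** is the temporal maximum of $c_{gw}$ over
the horizon; the study-level *exposure concentration* is the 95th percentile
of that peak across Monte Carlo draws, and the *exceedance probability* is
the fraction of draws whose peak exceeds the Class III limit.

## Parameters and defaults

| Parameter | Symbol | Unit | Default |
|---|---|---|---|
| Infiltration coefficient | $\alpha$ | – | N(0.2, 0.05), truncated at 0 |
| Annual precipitation | $P$ | mm/a | fixed 900 (base case) |
| Subgrade layer thickness | $d$ | m | U(0.3, 1.2) |
| Tailings volume fraction | $f$ | – | U(0.1, 0.5) |
| Subgrade material density | $\rho$ | kg/L | N(2, 0.2) |
| Cumulative liquid-to-solid ratio | – | L/kg | 100 |
| Soil bulk density | $\rho_b$ | kg/L | 1.5 |
| Water-filled porosity | $\theta_{ws}$ | – | 0.3 |
| Air-filled porosity | $\theta_{as}$ | – | 0.2 (inert while $H=0$) |
| Groundwater Darcy velocity | $U_{gw}$ | m/a | 25 |
| Mixing-zone thickness | $\delta_{gw}$ | m | N(2, 0.082) |
| Soil infiltration rate | $I$ | m/a | 0.3 (base case) |
| Road width | $W$ | m | U(3.5, 30) |
| Well distance | $x$ | m | 100 |
| Hydraulic conductivity | $K$ | m/d | U(10, 50) |
| Hydraulic gradient | $i$ | – | U(0.003, 0.006) |
| Effective porosity | $n$ | – | U(0.30, 0.50) |
| Longitudinal dispersion | $D_L$ | m²/d | U(5, 10) |

The hydraulic gradient and porosity are specified in per-mille and percent
in the source inventory and converted to dimensionless at construction. The
pollutant inventory (`default_pollutants()`) carries each metal's fitted
leachate normal distribution and Class III limit; the per-iteration leachate
concentration $C_j$ is drawn from that distribution, so source-strength
uncertainty propagates into the risk.

Transport operates internally in days; the exposure layer converts years to
days at exactly 365 d/a. The default horizon is 50 years with a 0.05 a grid
step — fine enough that the interpolated peak height is within about 1% of
the continuous-time maximum for these smooth breakthrough curves; both are
configurable.

## Regional scenarios and blend sweep

Four dry–wet regimes discretise the climate: humid (> 800 mm/a), semi-humid
(400–800), semi-arid (200–400), arid (< 200), each uniform within its band.
The two open-ended bands are closed at 1600 mm (roughly the wet end of
non-tropical monsoon climates) and 25 mm (hyper-arid floor); both are
configurable, and results for the inner regimes do not depend on them. In
regional mode the vadose infiltration rate is replaced by $q = \alpha P$
(`couple_infiltration = TRUE`) so precipitation consistently drives both
source depletion and vadose dilution — this is what creates the wet-to-dry
risk ordering.

The blend sweep fixes $f$ at each grid value (default 0.05–1.00 in steps of
0.05), re-runs the Monte Carlo simulation under a regime with a shared seed
(common random numbers keep the sweep smooth), and reports the
95th-percentile-peak-to-limit ratio; the management limit `f_max` is the
largest grid fraction with ratio at most 1. Because $\lambda$ decreases in
$f$ while the source term increases linearly, the peak is monotone
non-decreasing in $f$ and the threshold is well-defined.

## Monte Carlo engine

Each scenario symbol is sampled from its own RNG substream, derived from the
master seed in a fixed documented order. This makes runs bit-reproducible
for a given `(seed, config)` and *prefix-stable*: extending `n_iter` leaves
the first draws of every symbol unchanged. Normals are truncated at zero via
the inverse CDF on the conditional probability scale rather than by
rejection — exact, vectorised, and each draw consumes exactly one uniform
variate, which is what guarantees prefix stability. (All shipped normals
have mean at least three standard deviations above zero, so truncation bias
is negligible either way.) Percentiles are empirical with linear
interpolation (R's default type-7 quantile).

## Numerical choices

* The second term of $DAF$ is evaluated as
  $\exp(ux/D_L + \log \mathrm{erfc}(b))$ with $\log \mathrm{erfc}$ computed
  from the normal log-CDF, so the factor $e^{ux/D_L}$ never overflows; the
  tests exercise $ux/D_L$ up to 2000.
* $DAF$ is clamped to $[0,1]$ against last-ulp float excursions; $t \le 0$
  returns 0 by the pre-breakthrough convention.
* The verification oracle solves the advection–dispersion equation by
  Crank–Nicolson time stepping with central differences on a domain
  extending six dispersive standard deviations past the advective front,
  with a Dirichlet unit inlet. Grids must satisfy a cell Péclet number
  $\le 2$ and Courant number $\le 1$. At the default 1 m spacing it agrees
  with the analytic solution to better than $5\times10^{-3}$ absolute over
  the tested lattice of $(u, D_L, t)$.
* Degenerate inputs are handled explicitly: zero tailings fraction, zero
  leachate concentration, or zero precipitation yield an identically zero
  series (no release) rather than 0/0; a zero soil-water partition
  coefficient is a validation error pointing at the degenerate soil
  parameters.

## What the synthetic generator does and does not emulate

`generate_leaching_dataset()` draws i.i.d. truncated-normal leachate
concentrations per pollutant at the campaign size (n = 100 by default),
with optional detection-limit censoring (substituted at half the detection
limit in statistics, flagged in the data). It reproduces the *statistical
structure* the analysis assumes — normal per-pollutant variation around the
fitted means. It does not emulate spatial correlation between sampling
locations, inter-element correlation within a sample, pH-dependent
speciation, or heteroscedastic analytical error. Passing tests therefore
demonstrate that the pipeline correctly propagates the assumed structure,
not that field data satisfy those assumptions.

## Known limitations

* One-dimensional transport with no transverse dispersion, retardation or
  decay: conservative for peak concentration at the centreline.
* Annual-average forcing: no storm-scale or seasonal rainfall dynamics, so
  short high-intensity events in dry regions are outside scope.
* The equilibrium reading of the source–well coupling, the $C_0 = f C_j$
  link, and the closure of the open-ended climate bands are modelling
  choices where the source material is ambiguous; each is switchable in the
  configuration, and the acceptance script records which convention
  produced its numbers.
* Several published figures for this system are mutually inconsistent
  (hazard indices versus the printed summary statistics; percentile values
  labelled in mg/L that behave as ratios; regional peaks an order of
  magnitude above the same site's base-case percentiles). The package
  implements the stated definitions and reports its own computed values;
  the test suite asserts the recomputed quantities and leaves the
  irreconcilable comparisons visibly failing rather than tuning to them.

## Problem sizes used in the shipped tests

Unit and property tests run the Monte Carlo engine at a few hundred
iterations on a coarsened 30-year/0.5 a grid — the physics is smooth in
time, so this resolves peaks to a few percent while keeping the suite fast.
The acceptance-level checks use the full 10,000 iterations on the default
50-year/0.05 a grid, and the estimator-convergence check compares a 10,000-
iteration exceedance estimate against a 100,000-iteration reference within
its binomial confidence interval.
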