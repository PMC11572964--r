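---
title: "Methods: multi-scale cooling-efficiency estimation and power-law scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale cooling-efficiency estimation and power-law scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

Cooling efficiency (CE) at an analytical-unit size $S$ is defined
operationally: tile the study area with square units of side $S$,
compute per-unit percent tree-canopy cover $P_{tree}$ and mean
land-surface temperature (LST), and regress LST on $P_{tree}$ by
ordinary least squares with a free intercept. CE is the absolute value
of the slope, in °C per percentage point of cover. Across unit sizes CE
follows the power law

$$\mathrm{CE}(S) = k\,S^{\beta},$$

with normalization constant $k$ (°C/%UTC at $S = 1$ in the chosen size
unit) and dimensionless scaling exponent $\beta$. A sublinear exponent
($0 < \beta < 1$) means CE rises steeply across neighbourhood scales
and flattens toward the city scale, which is what makes extrapolation
to a whole-city planning number possible.

The regression is deliberately bivariate. The underlying claim is not
that canopy is the only control on LST but that the bivariate slope is
the quantity whose scale dependence is being characterized; adjusted or
spatial models estimate a different quantity and are out of scope. For
the same reason the standard errors are classical OLS by default — a
heteroskedasticity-robust (HC3) option exists on `estimate_ce()` but
does not alter the point estimates.

## The unit ladder and aggregation rules

Units are squares of $w \times w$ base pixels for odd widths
$w = 1, 3, 5, \dots, w_{\max}$ (`make_ladder()`); with a 120 m base
pixel and $w_{\max} = 23$ the ladder tops out at 2,760 m, with
$w_{\max} = 37$ at 4,440 m. The maximum should reflect the study-area
size: the largest unit must still tile the city several times over.
Even widths are available behind `odd_only = FALSE` for sensitivity
analysis only.

Aggregation choices that the measurement leaves open were fixed as
follows:

* **Anchoring.** Grids anchor at the raster's top-left corner; partial
  tiles at the right/bottom edges are discarded so every unit has equal
  support.
* **Validity.** A base pixel contributes only when LST and cover are
  both non-missing and inside the optional boundary mask. A unit is
  kept when its valid fraction is at least `min_valid_fraction`
  (default 0.5, the common half-support convention in zonal
  statistics); the threshold is a visible parameter, not a hidden rule.
* **No implicit resampling.** LST and canopy rasters must share a
  footprint to within half a base pixel and an exact integer resolution
  ratio; anything else is rejected. Fine binary canopy is reduced to
  fractional cover by exact counting (`coarsen_canopy()`), with base
  cells that are majority fine-nodata set to nodata.
* **Degenerate units.** A scale whose units have exactly zero
  $P_{tree}$ variance carries no slope information; such tables are
  flagged at aggregation time and skipped (with a warning) by
  `estimate_all()`, which requires at least three usable scales.

## Fitting, fallback, and pooling

The default fit space is log–log: OLS of $\ln \mathrm{CE}$ on $\ln S$,
the conventional linearization, giving closed-form 95% confidence
intervals ($k$'s by exponentiating the intercept bounds) and a
closed-form mean-response band reused by the prediction stage. A direct
nonlinear least-squares fit of $\mathrm{CE} = kS^\beta$ (initialized
from the log–log solution) is available by flag; points are unweighted
by default with an optional $1/\mathrm{se}^2$ weighting, since the
measurement itself prescribes neither.

Non-positive CE values cannot enter the log fit and are dropped with a
warning; if more than half would be dropped, the direct space is used
instead. `select_model()` keeps the power law when its scale term is
significant at $\alpha = 0.01$ and otherwise falls back to the
quadratic $c_0 + c_1 S + c_2 S^2$, whose significance is the joint
F-test of both scale terms. Because the exact "higher fitness"
criterion for the fallback is ambiguous, the selection logs both forms'
p-values and direct-space $R^2$ and keeps the rejected fit in
`$alternative`.

Multi-date pooling fits one power law to the pooled
$(\ln S, \ln \mathrm{CE})$ points across dates. The alternative —
averaging per-date parameters — is deliberately not the estimator;
per-date fits are returned alongside so their dispersion can be
reported either way.

## Prediction and goal inversion

`predict_ce()` evaluates the fitted law at an evaluation size
`s_city_m`, defaulting in the pipeline to the largest aggregated scale:
the analysis treats its largest units as the planning-relevant
"whole-city" scale rather than defining a separate city size (a
`sqrt(city area)` choice can be passed explicitly). The confidence
interval is the log-space mean-response band, exponentiated — for a
monotone transform this is exact, simpler and more conservative than a
delta-method band. Sizes beyond the fitted range warn as extrapolation;
quadratic fits are refused here because extrapolating a concave
quadratic is not meaningful.

The canopy goal for a target reduction $\Delta T$ is
$\Delta T / \mathrm{CE}(S_{city})$, with the interval obtained by
inverting the CE interval endpoint-wise (order flipped). Note that
re-dividing a *rounded* CE interval will not reproduce a goal interval
computed from unrounded values; the package always propagates unrounded
numbers.

## Weather covariates

Vapor pressure deficit uses the Magnus saturation-pressure
approximation with the WMO coefficient set
($e_s = 6.112\,\exp(17.62\,T/(243.12+T))$ hPa,
$\mathrm{VPD} = e_s(1 - \mathrm{RH}/100)$), chosen because the source
measurement reports VPD without a formula. Exponent–weather
relationships are Pearson correlations with two-tailed t-based
p-values, reported together with the OLS slope of exponent on
covariate, since the association of interest is linear.

## What the synthetic generators emulate

The **tabular generator** (`simulate_unit_tables()`) draws, per scale,
$P_{tree} \sim \mathrm{Uniform}(0, 100)$ (a Beta-shaped option exists)
and $\mathrm{LST} = a - kS^\beta P_{tree} + \varepsilon$ with Gaussian
noise, so the population slope at every scale is exactly $-kS^\beta$.
It validates estimation and fitting against a known truth; it does not
emulate spatial autocorrelation, shared units across scales, or
non-canopy LST drivers. The intercept is constant by default (a
per-scale-varying flag exists, matching the free intercepts of the
per-scale regressions). The residual noise level is nominal
(0.5 °C default) — the unit-level residual variance of real LST
regressions is not published, so recovery experiments state sampling
precision under the stated noise, not under field conditions.

The **raster generator** (`simulate_raster_pair()`) builds canopy as a
correlated Gaussian random field (FFT convolution of white noise with a
Gaussian kernel on a torus — the simplest field with a controllable
correlation range mimicking patch structure), thresholded at the
quantile matching the cover target, so realized cover hits the target
up to grid discretization. LST couples to cover through a local term
plus a term in the Gaussian-smoothed cover. The smoothed term is the
mechanism hook: at the base scale, smoothed cover is an imperfect proxy
for pixel cover and the bivariate slope under-counts it, while unit
means at scales well above the smoothing radius recover the full
effect — so estimated CE rises with scale, emulating the patch-size
dependence of evapotranspirative cooling. With the neighbourhood term
off, CE is exactly scale-free, which the tests use as the null case.
The generator makes no attempt at radiometry, atmospheric effects, or
image classification, so passing tests demonstrate statistical
machinery, not remote-sensing fidelity.

## Raster format

Rasters are read and written as Esri ASCII grids (`.asc`): a
plain-text, single-band format whose header carries the geotransform
(corner origin, square cell size) and nodata sentinel. The format
carries no CRS, so a CRS identifier is attached in memory only and
co-registration is validated purely on the grid geometry. Values
round-trip at 15 significant digits; binary canopy round-trips exactly.

## Problem sizes and numerical tolerances

The test suite's simulation sizes were chosen to make sampling error
negligible relative to the asserted tolerances: recovery experiments
use 200 replicates of 12 scales × 1000 units with 0.5 °C noise (the
per-replicate exponent scatter is then ≈ 0.001, so a ±0.01 band on the
mean is a >5σ margin); raster experiments use 60 × 60 base-pixel grids
with a 5-scale ladder (120–1080 m), large enough that the base scale
alone has 3,600 units. Exact-arithmetic contracts (aggregation versus a
per-tile double loop, OLS versus the normal equations, power-law
recovery from exact points) are asserted at 1e-9 to 1e-12; Monte-Carlo
contracts (CI coverage of a null exponent, permutation type-I rates)
are asserted at the bands their replicate counts support.

## Known limitations

* OLS ignores the spatial autocorrelation of unit residuals, so
  per-scale standard errors are optimistic on real rasters; the scaling
  fit also treats per-scale CE estimates as independent points even
  though nested units share pixels.
* Whether boundary-straddling units should be kept is genuinely open;
  the half-support default is a convention, and results at coarse
  scales in small cities can be sensitive to it.
* The quadratic fallback is descriptive; it should not be extrapolated,
  and the package refuses to.
* Synthetic calibration bounds what the estimator stack does under its
  own assumptions — it cannot validate the power law as a fact about
  any particular city.
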