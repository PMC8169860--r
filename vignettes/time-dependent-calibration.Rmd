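---
title: "Time-dependent cultivar parameter calibration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-dependent cultivar parameter calibration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcal)
```

## The problem

Mechanistic crop models simulate yield from weather, soil, management and a
set of *cultivar parameters* — genotype traits such as radiation use
efficiency or the thermal time between phenological stages. Conventional
calibration treats these as constants. Over decades, however, plant breeding
moves them steadily: a cultivar parameter fitted once to a 30-year county
yield record will average away the very trend that explains the observed
yield increase. `tdcal` estimates cultivar parameters as *functions of time*
from county-level yield series, and forecasts their next-year values so the
crop model can be run forward with up-to-date traits.

The package has four layers, each usable on its own:

1. an overlapping **time-window scheme** that turns a `Y`-year record into
   per-year parameter values,
2. a **parallel Bayesian optimization** (PBO) engine that calibrates each
   window against observed yields,
3. an **autoregressive trend model** per parameter with PACF order selection
   and an augmented Dickey-Fuller diagnostic, and
4. a **synthetic crop simulator** with known ground truth for validating the
   whole chain by parameter recovery.

## The time-window scheme

With main-window length `n` (default 5 years), main window `i` covers
training years `i .. i+n-1`, so successive main windows overlap by `n - 1`
years and `Y` years produce `Y - n + 1` main windows (30 for the 34-year
case-study layout). Edge years would be covered by fewer windows, so
shorter *auxiliary* windows are added: head auxiliaries covering years
`1 .. i-1` for `i = 2 .. n` and tail auxiliaries covering `i+n .. Y` for
`i = Y-2n+2 .. Y-n`. Under this assignment every year lies in exactly `n`
windows, which is the design invariant of the scheme.

```{r}
ws <- build_windows(windowing_config(Y = 34, n = 5))
ws
table(vapply(1:34, function(y) nrow(covering_windows(ws, y)), 0L))
```

The per-year parameter vector is a weighted average of the estimates of all
covering windows, with each window weighted by its length:

```{r}
year_weights(windowing_config(34, 5), 2)
```

For central years (`n <= y <= Y-n+1`) all covering windows are length-`n`
mains, so the combination reduces to a plain mean of `n` estimates, which is
what makes successive years' parameters change smoothly: two consecutive
years share `n - 1` of their `n` windows. The tail-auxiliary span and weight
(`Y - n - i + 1`, i.e. its length) are the unique choice that keeps both
stated properties — weights equal window lengths and every year covered by
exactly `n` windows — so the scheme is symmetric: the weight pattern at year
`y` is the reverse of the one at year `Y - y + 1`. The suite enforces this
by comparing the closed-form branches against a brute-force length-weighted
enumeration of covering windows.

`Y >= 2n` is required; for smaller `Y` the tail-auxiliary index range is
ill-formed, and the configuration is rejected rather than guessing a
degenerate scheme.

The choice of `n` is the bias-variance dial of the whole framework: longer
windows average more years per estimate (lower variance, higher bias against
a moving truth), shorter windows track faster but fit noise. The package
keeps `n` a plain configuration value; 5 years is the default.

## Parallel Bayesian optimization

Each window's parameters minimize the RMSE (kg/ha) between simulated and
observed county yields over the window's years. The objective is an
expensive black box (one call = one multi-year crop-model run), which is
Bayesian optimization territory. Plain BO is sensitive to its surrogate
choices: kernel family, kernel hyperparameters and acquisition function can
each change where it searches. PBO runs `N` BO instances with
*heterogeneous* (acquisition, kernel) pairs, and the instances share one
evaluation pool: every iteration each instance refits its Gaussian process
on *all* evaluations so far, proposes one point by maximizing its own
acquisition, and all `N` proposals are evaluated and pooled. The search thus
hedges across surrogate assumptions without spending `N` times the budget on
any one of them.

Numerical choices, all configurable:

* **Input scaling.** Parameters are scaled to the unit hypercube by their
  bounds; objectives are standardized to zero mean and unit variance at
  every refit. A single isotropic length scale is then meaningful across
  parameters whose physical units differ by five orders of magnitude.
* **Kernels.** Squared-exponential, Matérn-3/2 and Matérn-5/2; length scale
  and signal variance are refit by maximizing the log marginal likelihood
  (analytic gradients, L-BFGS-B, bounds `[1e-2, 1e2]` / `[1e-3, 1e3]` in
  scaled units) from each instance's declared starting values. Tuning can be
  disabled per instance (`tune_by_likelihood = FALSE`) to keep deliberately
  heterogeneous fixed hyperparameters.
* **Jitter.** The GP adds `1e-6` to the covariance diagonal (standardized
  scale), escalating tenfold up to `1e-2` if the Cholesky factorization
  fails; near-duplicate inputs (within `1e-8` in scaled space) are merged
  first.
* **Acquisitions.** Expected improvement and probability of improvement with
  margin `xi = 0.01`, and the lower-confidence-bound score with
  `kappa = 2.0`, all on the standardized objective scale. At `sigma = 0` the
  degenerate limits apply (`EI = max(f_best - mu - xi, 0)`, `PI` the
  indicator of improvement), so acquisition values are defined everywhere.
* **Inner maximization.** Multi-start bounded L-BFGS-B with analytic
  acquisition gradients, started from uniform-random points; the proposal is
  the best point over all runs *and* all start points, so more restarts can
  never propose worse. A proposal that duplicates an evaluated point (or an
  earlier proposal of the same iteration) is replaced by a uniform random
  point — a cheap exploration fallback.
* **Initial design.** One Latin hypercube of size `max(10, 2d)` shared by
  all instances; since instances share all findings anyway, a common design
  is the consistent choice.
* **Reproducibility.** Every random stream (design, restarts, fallbacks)
  derives from the master seed by fixed offsets, so `N`, `T` and seeds
  compose deterministically; the same seed gives a bit-identical trace.
* **Stopping.** `T` iterations by default; an optional improvement threshold
  stops early when one iteration improves the incumbent by less than the
  threshold. The default roster is `{EI, PI, LCB} x {Matérn-5/2,
  squared-exponential}` (`N = 6`), truncated or recycled for other `N`.

The single-instance baseline `run_bo()` is the same loop with `N = 1`; at
equal total budget on a smooth test objective, the pooled heterogeneous
search is expected to do at least as well, and the acceptance suite asserts
exactly that (median over a fixed seed list), not any particular margin.

## Trend modelling and forecasting

Each parameter's yearly series (per location) gets an autoregression

&nbsp;&nbsp;&nbsp;&nbsp;`x_y = beta0 + sum_{i=1..t} beta_i x_{y-i} + eps_y`

fitted by conditional least squares — exact on deterministic recursions,
which keeps the fit testable against hand-solved normal equations. The order
`t` is the largest lag whose partial autocorrelation exceeds the 95%
white-noise band `1.96 / sqrt(Y)` (sequential-regression PACF), capped at
`min(5, floor(Y/6))` and falling back to `t = 1` when nothing is
significant — the textbook cutoff; the source method names PACF without
fixing a rule. The augmented Dickey-Fuller test (constant-only regression,
AIC lag choice, MacKinnon 1994 p-values) is reported as a *diagnostic only*:
a short trending parameter series rarely rejects a unit root, and the trend
fit proceeds regardless. Forecasts beyond the training years substitute
recursively and are clipped into the parameter's physiological bounds (with
a flag), since an extrapolated trend must not push the crop model outside
its valid range. A linear-in-year fallback fitter is provided for
deliberately simple trend extrapolation.

Trend models are fitted per location rather than to a cross-location
average: locations differ in soil productivity, so their parameter series
are not exchangeable, and per-location fits keep the county aggregation
(median of locations, robust to outliers) at the yield level where it
belongs.

## The synthetic simulator and what it does (not) show

`generate_dataset()` emulates the case-study shape — 5 counties x 5
locations x 34 years — with a deliberately simple response:

&nbsp;&nbsp;&nbsp;&nbsp;`yield = base_potential x soil_factor x G(theta) x (1 + anomaly)`

where `G(theta) = 1 + sum_j w_j (u_j - 0.5)` is affine in the bound-scaled
parameters `u_j`. The fixed weights give radiation use efficiency (+0.30)
and the two grain components (+0.20 each) the dominant positive roles,
the reproductive-phase duration +0.15, small negative weights (-0.05) to the
three parameters whose historical trend runs downward, and zero weight to
grain N concentration and transpiration efficiency, which showed no
consistent direction. The true trajectory moves positive-weight parameters
linearly from scaled position 0.3 to 0.7 (negative-weight ones 0.7 to 0.3),
so `G` rises from 0.8 to 1.2 — a 1.5-fold yield increase over 34 years,
the shape of the historical county record. Defaults: county potential
`U(9000, 11000)` kg/ha, soil factors `U(0.85, 1.10)`, season anomalies
`N(0, 0.08)` per county-year, observation noise 250 kg/ha (~2.5% of mean
yield — small enough for trend recovery, large enough that window RMSEs are
never exactly zero).

Because `G` is the only channel from parameters to yield, any two parameter
vectors with equal `G` are observationally identical — *equifinality by
construction*, matching the identifiability limits of real crop-model
calibration. Recovery tests therefore target `G(P_y)`, never individual
components. Passing them shows the machinery — windowing, shared-pool
optimization, averaging, trend fitting — recovers a known smooth trend
through realistic noise; it does **not** show that a 9-parameter APSIM
calibration is identifiable, that real cultivar trends are linear, or that
the response of a real crop model is anywhere near affine. The simulator has
no weather files, soil-water dynamics or management inputs; an external
simulator is attached through the `crop_model_interface()` contract.

Two module-level facts worth knowing when reading test output: with a
trending truth, a *constant* parameter vector over an `n`-year window has an
irreducible RMSE floor (`base x` RMS deviation of `G*` within the window,
about 500 kg/ha at `Y = 12`), so per-window objectives are judged against
that floor, not against zero; and because calibration targets *county*
observations, a location's recovered `G` absorbs the ratio of county-mean to
local soil productivity — another reason recovery is asserted through
correlation with the true trend rather than absolute equality.

## Problem sizes used by the checks

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes that still exercise every code path
meaningfully: the 2-D quadratic benchmark with `N = 3`, `T = 30` (100
evaluations, 20 resp. 10 seeds for the equal-budget comparison); a
noise-free 1x1x12 dataset for per-window floor checks; and the default
5x5x34 dataset with `T = 15`, `N = 3`, 3 restarts, calibrating one location
per county for end-to-end trend recovery. Calibration is independent per
location, so the location subset changes cost, not the method; a full
25-location run is the same loop five times over.

## Known limitations

* Synchronous sharing only: proposals within an iteration use the pool from
  the previous iteration's end; there is no asynchronous variant, and
  wall-clock parallelism is not part of the contract.
* No observation-noise heteroscedasticity in the GP; the jitter is a single
  scalar.
* AR and linear trends only; no ARIMA/seasonal models, though the trend
  fitter slot accepts alternatives structurally.
* The ADF p-value is an asymptotic approximation; at `Y = 34` it is a rough
  diagnostic, which is one more reason it never gates the fit.
* The windowing scheme is contiguous and fixed-length by design;
  non-contiguous or variable-length schemes are out of scope.
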