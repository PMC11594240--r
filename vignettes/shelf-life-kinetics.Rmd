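---
title: "Degradation kinetics and Arrhenius shelf-life modelling with shelfkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degradation kinetics and Arrhenius shelf-life modelling with shelfkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shelfkin)
```

## The modelling problem

Accelerated storage studies monitor a quality index — here the
thiobarbituric-acid-reactive-substances (TBARS) value, in mg
malondialdehyde per kg, the standard secondary lipid-oxidation index of
fish and meat — at several constant temperatures, and extrapolate how long
a product remains acceptable. The chain has three links:

1. **Per-temperature kinetics.** At each temperature the index is assumed
   to follow zero-order (`A = A0 + k t`) or first-order
   (`A = A0 e^{k t}`) kinetics. [fit_kinetic()] estimates `k` by ordinary
   least squares of `A` (zero order) or `ln A` (first order) on time.
2. **Arrhenius temperature dependence.** The rate constants obey
   `k(T) = k0 exp(-Ea / (R T))`. [fit_arrhenius()] regresses `ln k` on
   `x_scale / T`; the slope gives the activation energy
   `Ea = -slope * x_scale * R` and the intercept the pre-factor
   `k0 = exp(intercept)`.
3. **Threshold shelf life.** The shelf life is the time for the index to
   travel from its time-zero value `a0` to the spoilage limit:
   `(ln a_limit - ln a0)/k` under first order, `(a_limit - a0)/k` under
   zero order ([predict_shelf_life()]), validated against observed shelf
   lives by the relative error `100 |pred - actual| / pred`
   ([relative_error()]).

```{r}
reg <- tbars_regressions()
eg <- reg[reg$group == "EG", ]
arr <- fit_arrhenius(data.frame(temperature = eg$temperature_K, k = eg$k))
arr
predict_shelf_life(a0 = 0.084, a_limit = 0.5, k = 0.06356, order = "first")
```

## Units and constants

* **Time is stored in hours.** Published per-temperature regression
  constants are only mutually consistent with published shelf lives when
  the time axis is hours at all temperatures (e.g.
  `ln(0.5/0.084)/0.00138 = 1292.6 h = 53.9 d` at 277.15 K); input files may
  use days (`time_unit = "d"`), which the reader converts.
* **Temperature is stored in kelvin**; files carry Celsius and are
  converted by exactly +273.15.
* **Gas constant** defaults to 8.3144 J/(mol K), the value conventional in
  this applied literature; it is configurable in [run_config()].
* **Arrhenius abscissa** defaults to `x_scale = 1000` (i.e. 1000/T), so the
  reported slope and intercept match the `y = a X + b` presentation of
  storage papers. `Ea` and `k0` are invariant to this choice; only the
  slope rescales.
* **Quality limit** defaults to 0.5 mg MDA/kg, the widely cited TBARS
  acceptability threshold.

## The hybrid "paper mode" of the pipeline

Published TBARS storage studies commonly *fit* the raw index linearly
(zero order) at each temperature but *predict* shelf life with the
first-order logarithmic formula. The two are theoretically inconsistent,
yet the published predictions only reproduce under exactly this hybrid.
[run_shelf_life_pipeline()] therefore has two modes:

* `paper_mode = TRUE`: per-temperature `k` from the zero-order fit,
  shelf life from the first-order formula — reproducing the published
  chain (28 h at 310.15 K from `k = 0.06356` and `a0 = 0.084`).
* default (`paper_mode = FALSE`): the configured order is used for both
  stages, which is the self-consistent choice for new analyses.

Two further conventions in this mode were genuinely open and are resolved
as follows. First, the time-zero value `a0`: all per-temperature
intercepts estimate the same quantity, and the published 310.15 K
prediction reproduces only with the refrigerated-condition intercept
(0.084) shared across temperatures; `a0_policy = "shared_value"` encodes
that, while the default uses each temperature's own intercept. Second,
predictions use each temperature's *fitted* rate constant
(`k_source = "fitted_per_temperature"`): the Arrhenius-smoothed rate at
310.15 K (0.0413/h) would give 43 h, not the published 28 h; [rate_at()]
exposes the smoothed rate for extrapolation to unobserved temperatures,
which is the Arrhenius fit's real purpose. Relatedly, the published
room-temperature predictions (2.7 d treated / 1.5 d control) are not
reproducible from the published constants under either pure order or the
hybrid; the package documents rather than imitates that inconsistency, and
no mode targets those two values.

## Numerical conventions

* OLS goes through `stats::lm`; `R^2 = 1 - SSres/SStot` with `SStot` about
  the mean. When the response has zero variance `R^2` is undefined; the
  package reports 0 with a warning.
* First-order fitting requires strictly positive values and names the
  offending time otherwise.
* Rates passed to the Arrhenius fit are sorted by temperature first — the
  fit is order-invariant, sorting only stabilizes reports.
* Shelf lives shorter than 72 h are reported to the nearest hour, longer
  ones in days with one decimal; relative errors default to whole percent
  (both conventions appear in validation tables).
* TVB-N freshness classes use strict "< 15" for fresh and strict "> 30"
  for spoiled, with the 15–30 band inclusive at both ends.

## NIPALS PLS2

[fit_pls2()] implements two-block partial least squares with multivariate
response by the NIPALS iteration: both blocks are autoscaled (sample
standard deviation, n−1 denominator; zero-variance columns scaled by 1
with a warning), components are extracted by alternating regressions until
the X-weight vector changes by less than `tol` (default 1e-10, cap 500
iterations — non-convergence is a recorded warning, not an error), and
both blocks are deflated on the X-scores, so per-component explained
variances are additive by construction. The sign of each component is
fixed by forcing the largest-magnitude weight element positive, making
output deterministic. [correlation_loadings()] returns the correlation of
each original variable with each score — the quantity plotted inside the
r² = 0.5 and r² = 1 circles of the conventional loading plot.

[pufa_design()] builds the storage-condition design over the bundled
fatty-acid tables: 14 unique (temperature, time) conditions (the three
identical time-zero conditions collapse to one baseline row, which carries
no temperature indicator), 17 zero/one condition indicators plus the
PUFA/SFA and SFA+MUFA indices (averaged over the two groups, computed from
the printed class totals) as X, and the 22 per-group acid percentages as
Y. The variance shares such a model reports depend on exactly this design
coding — dummy sets and baseline handling differ between software packages
— so they are reported for inspection rather than asserted against any
external figure.

```{r}
d <- pufa_design()
fit_pls2(d$X, d$Y, n_components = 2)
```

## What the synthetic generator emulates

[simulate_kinetic_dataset()] draws quality-index series from the exact
forward model the analysis assumes: Arrhenius-linked rate constants at
each design temperature, zero- or first-order growth, and additive and/or
multiplicative Gaussian noise. Defaults mirror the three-temperature
accelerated design of refrigerated fish storage — 277.15 K sampled at
0/72/144/216 h, 298.15 K at 0/12/24/36/48 h, 310.15 K hourly to 6 h — with
truth `Ea = 7.8364e4 J/mol`, `k0 = 6.5044e11 /h`, `a0 = 0.084 mg MDA/kg`.
The additive noise default of 0.01 mg MDA/kg is small relative to the
0.084→0.5 working range and gives per-temperature fits with R² around
0.95–0.99, matching the quality of published TBARS regressions. A draw at
or below zero is resampled once and then floored at 1e-6 with a warning.

[simulate_fa_profiles()] generates compositional drift on the simplex —
latent per-acid scores drifting linearly in time, pushed through a
softmax — so class closure (PUFA+SFA+MUFA = 100) holds exactly by
construction. [simulate_sensory()] maps a quality index affinely to a
score clamped to the rubric's attainable 40–100 range.
[recovery_experiment()] repeats simulate→fit with replicate seeds derived
as `seed + rep − 1`, so any subset of replicates is reproducible.

These generators deliberately omit several features of real storage data:
between-replicate biological variance beyond the single noise term,
autocorrelated measurement error, lag phases and plateaus in oxidation
curves, and any microbial or texture mechanics. Passing recovery tests
therefore demonstrate correctness of the estimation chain under the
model's own assumptions, not robustness to model misspecification.

## Problem sizes

The bundled tests run the recovery experiment at 200 replicates of the
three-temperature design (16 observations per replicate) and
property-style checks at 10–25 random instances each — sizes chosen so the
full suite completes in a few seconds while the stochastic summaries
(e.g. the <5 % activation-energy bias check) are stable across seeds of
the same magnitude.

## Known limitations

* The Arrhenius fit assumes a single rate-limiting mechanism across the
  temperature range; curvature in `ln k` versus `1/T` (mechanism change,
  phase transitions) is not modelled, and with only three temperatures the
  fit cannot detect it.
* Shelf-life uncertainty is not propagated; the pipeline reports point
  predictions plus empirical relative errors, as the source literature
  does.
* The fatty-acid tables bundled as fixtures print identical SFA/MUFA rows
  for the two groups at the accelerated temperature — carried verbatim as
  published, and worth remembering when interpreting analyses built on
  them.
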