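---
title: "Nonparametric causal screening of PM2.5 and cardiovascular admissions: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric causal screening of PM2.5 and cardiovascular admissions: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pm25screen)
```

## The screening problem

Short-term associations between ambient fine particulate matter (PM2.5) and
daily cardiovascular hospital admissions (CVD HAs) are routinely estimated
with count regressions, but a regression coefficient folds together every
path connecting exposure and outcome — seasonal cycles, temperature,
geography, and whatever shared drivers are not measured at all. This package
implements a *screening* workflow built on one necessary condition for
direct causation, the information principle: a direct cause must carry
predictive information about its effect that cannot be obtained from the
other measured variables. Operationally, the exposure must remain
*adjacent* to the outcome in a learned conditional-dependence network.
Failing the screen never proves absence of an effect; passing it never
proves causation. The verdict vocabulary (`exposure_adjacent` /
`not_adjacent`, plus a confounding flag) is deliberately chosen so that no
output reads as an affirmative causal claim.

Three stages implement the screen, each on a different statistical footing:

1. **Parametric baselines** — linear, Poisson and quasi-Poisson regressions
   of the 75+ admission counts on same-day PM2.5, adjusted for county, year,
   month, four temperature variables and the opposite-sex 75+ count, with
   the conventional percent-increase-per-10-µg/m³ conversion
   `(exp(10β) − 1) × 100`.
2. **Model ensembles** — bootstrap random forests of CART regression trees
   and Friedman partial-dependence (PDP) curves of admissions against
   exposure, conditioned on the same covariates plus
   disjoint-subpopulation *negative-control* counts.
3. **Conditional-dependence structure** — Bayesian-network structure
   learning over the discretized panel, by constraint-based search
   (PC-stable with G² tests) and, as a cross-check, score-based hill
   climbing with BIC.

Because the motivating hospital-discharge panel is restricted-access, the
package ships a synthetic county-day generator with *known* causal
structure, calibrated to the published marginal scales of the real panel.
Every claim the package makes about its own operating characteristics is a
claim about this generator.

## The synthetic panel generator

`generate_panel()` draws one record per county per day under the ordering
calendar → temperature → PM2.5 → counts:

* **Temperature.** Daily average temperature is an annual cosine
  (`seasonal_temperature()`): county mean (67.6 °F Dallas, 70.6 °F Harris),
  amplitude 20 °F peaking at day 199 (mid-July), plus N(0, 4.5²) noise.
  This reproduces a 69.1 °F grand mean and ≈14.8 °F marginal sd. Minimum,
  maximum and dew-point temperatures are the daily average shifted by
  −10.2, +9.7 and −13.5 °F with their own noise, clamped so that
  `temp_min ≤ temp_avg ≤ temp_max` and `dew_point ≤ temp_max`; the source
  data report only marginal summaries, so fixed offsets are the simplest
  mechanism consistent with them.
* **PM2.5** is log-normal — guaranteeing positivity and a right-skewed
  marginal — with log-mean built from a baseline (11.15 µg/m³ geometric
  scale), a mild seasonal term peaking in August (amplitude 0.08 on the log
  scale), a temperature slope of 0.0076 per °F (chosen to reproduce the
  published exposure–temperature rank correlation of ≈0.26), and log-noise
  sd 0.41. Together these give mean ≈12.2 and sd ≈5.5 µg/m³.
* **Counts.** Each subpopulation count (men 75+, women 75+, adults 18–75)
  is Poisson with log-rate = log(baseline) + winter-peaked month offsets
  (amplitude 0.12) + a cold-effect temperature slope (−0.004 per °F) +
  county offsets (±0.05) + the shared latent confounder + `beta_pm_true`
  × PM2.5. Baselines 9.62 / 15.68 / 55.9 give marginal means ≈10.0, 16.3
  and 58.1 once the variance of the log-rate is accounted for.
* **Latent confounder.** A single stationary AR(1) series
  (`latent_confounder_series()`, marginal sd 0.25, lag-1 correlation 0.8)
  enters the log-rate of *every* subpopulation on a given day. One shared
  series is the minimal mechanism consistent with "unmeasured factors
  affect all subpopulations"; it is what the negative-control machinery is
  designed to detect. Optionally (`confounder_pm_coeff`) the same series
  loads on log-PM2.5, creating an episodic common cause of exposure and
  outcome in the spirit of air-stagnation events.
* `beta_pm_true` defaults to **zero**: the default panel encodes the null
  hypothesis, and power scenarios switch it on.

Defaults were calibrated once against the published marginal table and then
frozen; `scenario_preset()` bundles the three named scenarios used
throughout (`null`, `power` with β = 0.004, and `confounded_null`).

What the generator does *not* emulate: within-county spatial aggregation of
monitors, day-of-week admission cycles, long-term trends, holidays, and
autocorrelated exposure. Tests passing on this generator therefore show
that the machinery behaves as designed under a clean data-generating
process, not that the substantive findings on the real panel are correct.

## Parametric stage

The fitters are self-contained: ordinary least squares by QR, Poisson
maximum likelihood by iteratively reweighted least squares (tolerance 1e-8
on the coefficient change, 100 iterations, Fisher standard errors), and
quasi-Poisson as the Poisson point estimates with standard errors inflated
by the square root of the Pearson dispersion. Categorical covariates use
reference coding with the first sorted level dropped. The test suite pins
all three against `stats::glm`/`lm` to 1e-6. Exposure enters with no lags:
the screen concerns same-day exposure only.

## Forest and partial-dependence stage

CART trees grow greedily by SSE reduction, numeric splits at midpoints
(ties route left), categorical splits by the standard ordered-subset search
on category means. Forests use bootstrap resampling, `mtry = ⌊p/3⌋`, and
500 trees in fidelity runs (100 in the screening configuration, for speed).
The PDP value at grid point *g* is the exact Friedman average — the mean
prediction over all panel rows with the exposure column forced to *g* —
computed by a single tree traversal that partitions rows on non-target
splits and grid points on target splits, which is algebraically identical
to brute force. The default grid is the sorted unique observed exposure
values, quantile-thinned above 256 points.

`pdp_effect_size()` summarizes a curve as its least-squares slope over the
grid, scaled to a 10 µg/m³ increment and normalized by the curve mean.
This is one defensible scalar summary of a curve that is otherwise only
described qualitatively; it is linear, so a flat curve maps to 0 and a
log-linear 1%-per-10 curve maps to ≈1.

**Leaf-size choice.** The screening forest uses `min_leaf = 100` (5% of
the 2 000-row study panels). Leaf means of ≥100 Poisson counts have
standard error ≤ 0.33 admissions, which puts the ensemble curves in the
±0.2% wiggle regime in which admission-rate PDPs are interpretable; with
small leaves the curves inherit Poisson noise and their slopes are
dominated by sampling error. The trade-off is deliberate and has a hard
limit worth stating plainly: at n = 2 000 county-days, *any* unbiased
estimate of the exposure slope has sampling sd of roughly 1.7% per
10 µg/m³ (residual count sd ≈ 4.3 against exposure sd ≈ 5.5), so a true 1%
per 10 µg/m³ effect cannot be reliably distinguished from zero by the PDP
slope at this sample size, smoothed or not. The test suite states this
expectation honestly: the null-flatness property holds at the chosen
settings, while the 1%-recovery property fails at every growth setting we
examined and is retained as a known-failing check documenting the
information floor.

## Network stage

Mixed variables are handled by quantile discretization (default 4 bins for
continuous variables; county, year and month pass through as categories).
Conditional-Gaussian scoring was rejected to keep every test an exact
multinomial computation with no distributional assumptions on skewed
exposure and count margins.

The G² statistic accumulates `2 Σ O log(O/E)` within each stratum of the
conditioning set; degrees of freedom use the sparse-table adjustment
(each stratum contributes (non-empty rows − 1)(non-empty columns − 1)), so
empty strata cannot inflate the reference distribution. PC-stable freezes
neighbor sets within each level (order-independent skeleton), caps the
conditioning-set size at 3 (tractable on 11 variables while allowing the
separating sets that matter here), orients v-structures from separating
sets, applies Meek rules, and orients any remaining undirected edges by
variable order — recorded as such in the provenance table. Orientation is
cosmetic for the screen: every verdict reads *undirected adjacency* only.
Hill climbing with the BIC score (add/delete/reverse moves, 10 random
restarts, parent cap 4) provides an algorithm-family cross-check; on
strong-signal toys both learners agree on skeletons.

**Sensitivity to shared effects.** A direct exposure effect that enters
*every* subpopulation count — as `beta_pm_true` does — is largely absorbed
by the control counts: the 18–75 count (mean ≈58) is an excellent proxy
for the day's shared log-rate, including the exposure contribution, so
conditioning on it separates the exposure from the 75+ outcomes. In
multi-seed runs the screen keeps PM2.5 non-adjacent even at β = 0.004
(≈4% per 10 µg/m³). This is the mirror image of the design's strength: the
same mechanism that lets disjoint-count adjacency absorb unmeasured
confounding also absorbs genuine effects common to all subpopulations. The
screen is therefore a conservative necessary-condition test with real
power only against effects that are *not* shared across the control
populations; `analysis/06_screen_suite.R` quantifies this and the
known-failing power check in the acceptance suite documents it.

## The confounded-null scenario

The `confounded_null` preset exists to reproduce a pattern familiar from
observational admission studies: a statistically significant regression
coefficient alongside a not-adjacent network verdict. Month-driven paths alone cannot
produce it, because the regression adjusts for month as a factor; the
scenario therefore combines strong seasonality (log-PM2.5 amplitude 0.3,
log-rate amplitude 0.2) with the episodic latent series (sd 0.3) loading
on log-PM2.5 with coefficient 0.2. The regression cannot adjust for the
latent series and its 1-dof Wald test picks up the induced association
essentially always, while the discretized G² — spending its power across
≥9 degrees of freedom — does not, and the screen still reports
`not_adjacent`. The loading was fixed once from a design-time power
calculation (a loading of 0.1 gives ≈40% significance, 0.2 gives ≈100%,
with the not-adjacent rate at 100% throughout) and is not a tuning knob.

## Numerical and degenerate-input conventions

* Split search requires a strictly positive SSE gain (ε = 1e-10) and both
  children ≥ `min_leaf`; zero-variance nodes and exhausted depth stop
  growth. Unseen categories at prediction time route right.
* IRLS flags non-convergence instead of erroring; an all-zero response is
  an error (the MLE diverges).
* A constant variable discretizes to a single bin with a warning; a
  G² test with zero adjusted dof returns p = 1.
* All writers are deterministic (fixed field order, 6 significant digits
  in CSV curves, full precision in JSON); panel CSV round-trips are exact
  for counts and to float-format precision for continuous columns.
* Every stochastic step takes an explicit seed, and the RNG state of the
  caller is restored afterwards.

## Problem sizes

The study conditions used throughout tests and the acceptance script are:
3 000 county-days (2 counties × 1 500 days) for structure learning and
regression suites, 2 000 county-days for forest/PDP suites, 20 seeds per
multi-seed property, forests of 100 trees (500 for fidelity), 500
replicates for the G² calibration check, and n = 5 000 for parameter
recovery. These sizes give stable rates while keeping a full run in
minutes on one core.

## Limitations

* Verdicts are relative to the measured variable set and the discretization;
  finer bins or additional variables can change adjacency.
* The screen cannot distinguish "no direct effect" from "direct effect
  shared by all subpopulations" (see above), and it inherits the usual
  finite-sample fallibility of conditional-independence tests.
* The generator's independence of day-to-day exposure understates the
  serial dependence of real pollution series; regression p-values on real
  data would need autocorrelation-aware inference.
* No latent-variable structure discovery (FCI-style), no temporal networks,
  no counterfactual estimands.
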