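# pm25screen

Nonparametric causal screening of short-term fine-particulate (PM2.5)
exposure against daily cardiovascular-disease hospital admissions (CVD HAs)
in county-day panel data — for air-pollution epidemiologists and
biostatisticians who want to go beyond a single regression coefficient when
judging whether an exposure–outcome association could be causal.

## The method

A regression coefficient between daily PM2.5 concentration *C* and an
admission count *R* summarizes **every** path connecting them: seasonality,
temperature, geography, and unmeasured common causes. The screen implemented
here rests on one *necessary* condition for direct causation (the
information principle): if

&nbsp;&nbsp;&nbsp;&nbsp;*R* ⫫ *C* | **Z**

for a covariate vector **Z**, there is no evidence that *C* is a direct
cause of *R*. Three stages apply this idea with progressively weaker
assumptions:

1. **Parametric baselines.** Linear, Poisson and quasi-Poisson regressions
   of the 75+ counts on same-day PM2.5, adjusted for county, year, month,
   average/min/max/dew-point temperature, and the opposite-sex 75+ count.
   Log-linear coefficients are reported as percent increases per 10 µg/m³,
   (e^{10β} − 1)·100.
2. **Model ensembles.** Bootstrap random forests of CART regression trees
   with exact Friedman partial-dependence curves of admissions vs PM2.5,
   conditioned on the covariates **and** on admission counts of *disjoint*
   subpopulations — negative controls that absorb unmeasured common causes.
3. **Conditional-dependence structure.** A Bayesian network learned over the
   discretized panel (PC-stable with G² conditional-independence tests;
   hill climbing with BIC as a cross-check). The screen's verdict is pure
   adjacency: `exposure_adjacent` if an arrow connects PM2.5 to an outcome
   in either direction, otherwise `not_adjacent`. Adjacency among disjoint
   subpopulation counts — which cannot cause one another — raises a
   confounding flag.

Because the motivating hospital-discharge panel is restricted, the package
includes a calibrated synthetic county-day generator with known causal
structure (seasonal temperature, month/temperature-driven log-normal PM2.5,
Poisson counts, a shared latent AR(1) confounder, and a configurable true
exposure effect, default zero). All operating characteristics are
demonstrated on it.

## Worked example

```r
library(pm25screen)

cfg    <- scenario_config(seed = 7)          # calibrated null scenario
panel  <- generate_panel(cfg)                # 3000 county-days
report <- run_screen(panel, screen_config(seed = 7))
print(report)
#> <screen_report>
#>   verdicts:
#>     count_m75: not_adjacent
#>     count_f75: not_adjacent
#>   confounding flag: TRUE
```

The panel reproduces the marginal scales of the Dallas/Harris study panel
(men 75+: mean 10.0, sd 4.3 daily admissions here; PM2.5 mean 12.3 µg/m³).
The three stages disagree in exactly the instructive way:

```r
report$regressions$count_f75$quasipoisson[c("beta", "percent_increase", "p_value", "dispersion")]
#> beta = 0.00133 (95% CI -0.00080, 0.00347), 1.34% per 10 ug/m3, p = 0.22, dispersion = 1.60
report$pdp$count_m75$pm25$effect_size_per_10   # -0.030  (% per 10 ug/m3)
report$pdp$count_f75$pm25$effect_size_per_10   # +0.036
```

The quasi-Poisson stage shows a positive (here non-significant) women's
coefficient of 1.34% per 10 µg/m³; the forest curves are flat at the
admission baselines (10.0 and 16.4 admissions/day); and the network keeps
PM2.5 non-adjacent to both outcomes while the 75+ counts remain adjacent to
each other and to the 18–75 count — the signature of the shared latent
confounder, correctly flagged. Under the `confounded_null` preset the
regression coefficient becomes reliably *significant* while the verdict
stays `not_adjacent`: a significant association with no adjacency support.

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end and write
tables under `results/`:

| script | output |
|---|---|
| `01_simulate_panels.R` | the three scenario panels + configs (CSV/YAML) |
| `02_descriptives.R` | per-variable summary table, Spearman matrix |
| `03_parametric_models.R` | regression table with percent increases |
| `04_forest_pdp.R` | PDP curves (CSV) and effect sizes |
| `05_network_structure.R` | learned structure (DOT/GraphML), verdicts |
| `06_screen_suite.R` | multi-seed verdict/flag rates per scenario |

```sh
Rscript analysis/01_simulate_panels.R 1 && Rscript analysis/05_network_structure.R
```

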