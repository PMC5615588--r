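Package: pm25screen
Title: Nonparametric Causal Screening of Short-Term PM2.5 Exposure and
    Cardiovascular Hospital Admissions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for screening short-term fine particulate matter (PM2.5)
    exposure as a candidate direct cause of daily cardiovascular-disease
    hospital admissions in county-day panel data. Provides a calibrated
    synthetic panel generator with known causal structure (seasonal
    temperature, month- and temperature-driven PM2.5, Poisson admission
    counts, an optional shared latent confounder); parametric baselines
    (linear, Poisson, quasi-Poisson regression with percent-increase
    conversion); self-implemented CART regression trees, bootstrap random
    forests and Friedman partial-dependence curves with
    disjoint-subpopulation negative controls; Bayesian-network structure
    learning over discretized panels (PC-stable with G-squared
    conditional-independence tests, and score-based hill climbing with BIC);
    and an orchestrated screen that reports adjacency verdicts and
    confounding flags.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
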