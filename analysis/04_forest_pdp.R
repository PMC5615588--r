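#!/usr/bin/env Rscript
# Random-forest partial-dependence analysis: for each 75+ outcome, fit a
# bootstrap forest conditioned on calendar, temperature and the disjoint
# control counts, then trace the partial effect of same-day PM2.5 and of
# the 18-75 control count. Effect sizes are normalized curve slopes in
# percent per 10 units.

suppressPackageStartupMessages(library(pm25screen))
args <- commandArgs(trailingOnly = TRUE)
n_trees <- if (length(args)) as.integer(args[[1]]) else 100L  # 500 = fidelity

panel <- read_panel_csv("results/panels/null.csv")
dir.create("results/pdp", showWarnings = FALSE, recursive = TRUE)

for (outcome in c("count_m75", "count_f75")) {
  controls <- setdiff(c("count_m75", "count_f75", "count_1875"), outcome)
  X <- panel[, c("county", "year", "month", "temp_avg", "temp_min",
                 "temp_max", "dew_point", "pm25", controls)]
  for (v in c("county", "year", "month")) X[[v]] <- factor(X[[v]])
  forest <- fit_random_forest(X, panel[[outcome]], n_trees = n_trees,
                              min_leaf = 100, seed = 1)
  for (feat in c("pm25", "count_1875")) {
    curve <- partial_dependence(forest, panel, feat)
    write_pdp_csv(curve, file.path("results/pdp",
                                   sprintf("%s_vs_%s.csv", outcome, feat)))
    cat(sprintf("%s vs %-11s baseline %6.2f admissions/day, effect %+.3f%% per 10\n",
                outcome, feat, attr(curve, "baseline"),
                pdp_effect_size(curve)))
  }
}
cat(sprintf("\nForest of %d trees; curves under results/pdp/.\n", n_trees))
cat("Near-flat PM2.5 curves at the admission baselines, with a clearly\n")
cat("positive dependence on the 18-75 control count, indicate shared\n")
cat("unmeasured drivers rather than a direct exposure effect.\n")
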