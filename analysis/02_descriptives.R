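#!/usr/bin/env Rscript
# Descriptive statistics of the null panel: per-variable summary table and
# the Spearman correlation matrix of PM2.5 with the meteorological factors.

suppressPackageStartupMessages(library(pm25screen))
panel <- read_panel_csv("results/panels/null.csv")

summ <- summarize_panel(panel)
dir.create("results", showWarnings = FALSE)
write.csv(format(summ, digits = 4), "results/descriptives.csv",
          row.names = FALSE, quote = FALSE)
print(summ, digits = 3)

rho <- spearman_matrix(panel)
write.csv(round(rho, 3), "results/spearman.csv", quote = FALSE)
cat("\nSpearman correlations (PM2.5 and meteorology):\n")
print(round(rho, 2))
cat("\nwritten: results/descriptives.csv, results/spearman.csv\n")
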