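#!/usr/bin/env Rscript
# Parametric baselines: linear, Poisson and quasi-Poisson regressions of the
# 75+ admission counts on same-day PM2.5, adjusted for county, year, month,
# the four temperature variables, and the opposite-sex 75+ count. Poisson
# coefficients are converted to percent increases per 10 ug/m3.

suppressPackageStartupMessages(library(pm25screen))
panel <- read_panel_csv("results/panels/null.csv")

rows <- list()
for (outcome in c("count_f75", "count_m75")) {
  dm <- build_design_matrix(panel, design_spec(outcome))
  fits <- list(linear = fit_linear(dm$X, dm$y),
               poisson = fit_poisson_irls(dm$X, dm$y),
               quasipoisson = fit_quasipoisson(dm$X, dm$y))
  for (fam in names(fits)) {
    f <- fits[[fam]]
    b <- f$coefficients[["pm25"]]; se <- f$se[["pm25"]]
    rows[[length(rows) + 1]] <- data.frame(
      outcome = outcome, model = fam, beta = b,
      ci_low = b - 1.96 * se, ci_high = b + 1.96 * se,
      p_value = 2 * pnorm(-abs(b / se)),
      pct_per_10ug = if (fam == "linear") NA
                     else percent_increase_per_10ug(b),
      dispersion = f$dispersion)
  }
}
tab <- do.call(rbind, rows)
write.csv(format(tab, digits = 4), "results/regression_table.csv",
          row.names = FALSE, quote = FALSE)
print(tab, digits = 3)
cat("\nUnder the null scenario every PM2.5 coefficient should be small and",
    "\nnon-significant; the quasi-Poisson dispersion exceeds 1 because the",
    "\nlatent confounder overdisperses the daily counts.\n")
cat("written: results/regression_table.csv\n")
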