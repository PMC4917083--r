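#!/usr/bin/env Rscript
# Consolidation-score analyses of the simulated cohorts: factorial ANOVA on
# the signed-root transformed gain (last-3 endpoint, best-3 control), simple
# effects, per-group t-tests and the correlation panel with the Fisher
# r-to-z comparison of the age correlations.

library(taplearn)

seed <- 20160622
dir.create("results/consolidation", showWarnings = FALSE, recursive = TRUE)

for (scen in c("main", "control1", "control2")) {
  cfg <- analysis_config(
    trials_path = sprintf("results/data/%s/trials.csv", scen),
    factors_path = sprintf("results/data/%s/factors.csv", scen),
    seed = seed, skip_fit = TRUE,
    out_dir = file.path("results/consolidation", scen))
  b <- run_full(cfg)
  a <- b$consolidation_anova
  cat(sprintf("\n== %s (%d subjects; factors: %s)\n", scen,
              nrow(b$subjects), paste(b$anova_factors, collapse = ", ")))
  for (eff in c("piano", "age_group", "piano:age_group")) {
    row <- a[a$effect == eff, ]
    if (nrow(row))
      cat(sprintf("  %-17s F(1,%d) = %6.2f, p = %.4g\n",
                  eff, row$df_den, row$F, row$p))
  }
  if (!is.null(b$correlations$age_fisher)) {
    fz <- b$correlations$age_fisher
    cat(sprintf("  age-corr compare  z = %.2f, one-tailed p = %.3f\n",
                fz$statistic, fz$p))
  }
}
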