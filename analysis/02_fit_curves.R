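#!/usr/bin/env Rscript
# Fit the hierarchical power-law learning-curve model to the main cohort's
# training data (16 hyperparameter groups, 2 chains) and compare the
# per-subject posterior means with the generator's ground truth.

library(taplearn)

seed <- 20160622
trials <- read_trials("results/data/main/trials.csv")
subjects <- read_factors("results/data/main/factors.csv")

fit <- mcmc_fit(trials, fit_grouping(subjects),
                mcmc_config(n_chains = 2, n_iter = 4000, n_burnin = 1000,
                            seed = seed))
sm <- summarize_fit(fit)

dir.create("results/fit", showWarnings = FALSE, recursive = TRUE)
write.csv(sm$summary, "results/fit/fit_summary.csv", row.names = FALSE)
write.csv(sm$estimates, "results/fit/estimates.csv", row.names = FALSE)

truth <- yaml::read_yaml("results/data/main/ground_truth.yaml")
tru_I <- unlist(truth$subject_params$I)
ids <- unlist(truth$subject_params$subject_id)
est_I <- sm$estimates$I[match(ids, sm$estimates$subject_id)]
cat(sprintf("posterior-mean I vs truth: r = %.3f, rmse = %.2f\n",
            cor(est_I, tru_I), sqrt(mean((est_I - tru_I)^2))))

mu_rows <- grepl("^mu_", sm$summary$parameter)
cat(sprintf("worst R-hat over group-level means: %.3f\n",
            max(sm$summary$rhat[mu_rows], na.rm = TRUE)))

tabs <- curve_param_anovas(sm$estimates, subjects, n_train = 12)
for (nm in names(tabs)) {
  write.csv(as.data.frame(tabs[[nm]]),
            sprintf("results/fit/anova_%s.csv", nm), row.names = FALSE)
  piano <- tabs[[nm]][tabs[[nm]]$effect == "piano", ]
  cat(sprintf("piano effect on %-11s F(1,%d) = %7.2f, p = %.4g\n",
              nm, piano$df_den, piano$F, piano$p))
}
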