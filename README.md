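# taplearn

Analysis toolkit for sequential finger-tapping motor-learning experiments
with a delayed retest: who learns faster on day one, and who keeps the gain
after a consolidation interval?

The package targets 2x2x2x2 factorial cohorts (piano experience x
dichotomized age x intelligence x gender) of the kind used to study whether
prior motor expertise protects overnight procedural-memory consolidation
against age-related decline. It provides three layers:

* **`synthgen`** -- a seeded generator of balanced factorial cohorts with
  fully recorded ground truth: per-subject power-law learning curves with
  group-dependent hyperparameters, and configurable overnight consolidation
  gains per design cell (`generate_design()`, `scenario_cohort()`,
  `write_cohort()`).
* **`curvefit`** -- a hierarchical Bayesian model of day-1 learning,

  `Y(t) = I + C (1 - R^(t-1)) + noise`,

  with subject parameters drawn from per-group normal distributions and all
  hyperparameters estimated per group. Fitting is by an adaptive
  Metropolis-within-Gibbs sampler (compiled, seeded, deterministic), with
  split-chain R-hat and rank-normalized effective sample sizes
  (`mcmc_fit()`, `summarize_fit()`, `log_density()`).
* **`inferstats` / `pipeline`** -- the downstream statistics: consolidation
  scores (mean of the three retest trials minus the mean of the last or
  best three training trials), the signed square-root transform, effect-coded
  factorial ANOVA with partial sums of squares, simple effects against the
  pooled residual mean square, one-sample t-tests, Pearson correlations and
  the Fisher r-to-z comparison of two correlations; orchestrated end to end
  by `run_full()` and `report()`.

## Worked example

The numbered scripts under `analysis/` run the full study pipeline on
simulated cohorts (`Rscript analysis/01_simulate.R` ... `04_report.R`).
In the main scenario, 128 subjects are generated with a mean overnight gain
of 3 sequences/trial everywhere except older non-players, who sit 2 lower --
prior experience compensates the age decline. The consolidation ANOVA on the
transformed scores then shows exactly the expected signature (seed 20160622):

```
== main (128 subjects; factors: piano, age_group, intelligence, gender)
  piano             F(1,117) =  11.39, p = 0.001002
  age_group         F(1,117) =   8.07, p = 0.005304
  piano:age_group   F(1,117) =   5.52, p = 0.0205
  age-corr compare  z = -2.24, one-tailed p = 0.012
```

i.e. a piano benefit, an age deficit, their interaction, and a stronger
age-related decline of the gain among non-players (negative z). Simple
effects attribute the piano benefit to the older group
(F(1,117) = 16.4, p < 1e-4) and not the younger (F = 0.53, p = 0.47).
The 30-minute-delay control cohort (unbalanced 20/20/14/13 recruitment,
residual df 56) keeps the age effect but shows no piano effect, matching its
generative configuration:

```
== control1 (67 subjects; factors: piano, age_group, intelligence, gender)
  piano             F(1,56) =   0.10, p = 0.7497
  age_group         F(1,56) =  11.18, p = 0.001479
```

On the model side, `analysis/02_fit_curves.R` fits the hierarchical curve
model to the main cohort (2 chains x 4000 iterations) and recovers the
generator's subject-level initial performances with r = 0.97
(RMSE 0.85 sequences/trial); the factorial ANOVA over the fitted parameters
detects the configured group differences in initial performance and
learning rate but none in total day-1 improvement.

A scalar worked example: comparing an age-gain correlation of -0.448
(n = 64) against -0.167 (n = 64),

```r
fisher_z_compare(-0.448, 64, -0.167, 64, tail = "one")
#> z: statistic = -1.732, df = -, p = 0.04164 (one-tailed)
```

## Repository layout

```
R/, src/          package code (generator, sampler, statistics, pipeline)
analysis/         numbered narrative drivers writing under results/
tests/testthat/   unit, property and acceptance tests
scripts/          acceptance.R
vignettes/        methods vignette (model, assumptions, design choices)
```
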