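Package: taplearn
Title: Hierarchical Learning-Curve Modelling and Consolidation Analysis for Sequential Finger-Tapping Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing sequential finger-tapping motor-learning
    experiments with a delayed retest. Provides a seeded generator for balanced
    factorial cohorts with known ground-truth power-law learning curves and
    overnight consolidation gains; a hierarchical Bayesian learning-curve model
    (Y = I + C(1 - R^(t-1))) fitted by an adaptive Metropolis-within-Gibbs
    sampler with rank-normalized convergence diagnostics; the downstream
    consolidation statistics (signed-root transformed gain scores, effect-coded
    factorial ANOVA with simple effects, one-sample t-tests, Pearson
    correlations, and the Fisher r-to-z comparison of two correlations); and an
    end-to-end simulate-fit-analyze-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    emmeans,
    withr
Config/testthat/edition: 3
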