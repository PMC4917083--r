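---
title: "Modelling motor-sequence learning and overnight consolidation with taplearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling motor-sequence learning and overnight consolidation with taplearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taplearn)
```

## The scientific problem

In a sequential finger-tapping experiment, participants repeatedly tap a
short digit sequence during timed trials; the performance measure is the
number of correctly completed sequences per 30 s trial. A training session of
12 trials (6 in the short-training variant) on day one is followed by a
3-trial retest after a consolidation interval (24 h, or 30 min in a control
design). Two quantities carry the science:

* **online learning** -- the within-session improvement on day one, and
* **offline consolidation** -- the performance change from the end of
  training to the delayed retest, with no intervening practice.

taplearn implements a complete, testable analysis chain for such designs:
a synthetic-cohort generator with known ground truth, a hierarchical Bayesian
learning-curve model, and the downstream consolidation statistics.

## The learning-curve model

Day-1 performance of subject $s$ on trial $t$ is modelled around a power-law
learning curve

$$Y_{st} = I_s + C_s\,(1 - R_s^{\,t-1}) + \varepsilon_{st}, \qquad
\varepsilon_{st} \sim \mathcal N(0, \sigma_{\mathrm{obs},g(s)}^2),$$

where $I_s$ is the initial performance at trial one (sequences/trial),
$C_s$ the change across the session (so $I_s + C_s$ is the asymptote), and
$R_s \in (0,1)$ the learning rate -- smaller values mean the plateau is
approached faster. Subject parameters are exchangeable within groups:
$I_s \sim \mathcal N(\mu_{g,I}, \sigma_{g,I}^2)$ and likewise for $C_s$ and
$R_s$, with hyperparameters estimated independently per group. By default a
group is one of the 16 cells of the factorial design; `fit_grouping(by=)`
coarsens this (e.g. to the four piano-by-age groups) when cells are small.

Several pieces of this model are genuinely open choices and are fixed as
follows:

* **Likelihood.** Performance counts are treated as continuous with additive
  Gaussian noise and one observation SD per group (symmetric with the
  per-group hyperparameters). Counts are not rounded by default, so the
  generator and the likelihood are exactly self-consistent.
* **Hyperpriors.** $\mu_I, \mu_C \sim \mathcal N(0, 10^2)$,
  $\mu_R \sim \mathrm{U}(0,1)$, and every SD (subject-level and observation)
  is Half-Normal$(0, 5^2)$. These are weakly informative on the scale of the
  task, where even expert performance stays below a few tens of sequences
  per trial.
* **Support handling.** $R_s$ is updated on the logit scale (with the
  matching Jacobian) so proposals never hit the $(0,1)$ boundary; the target
  density over $(I, C, R)$ is exactly `log_density()`, which returns
  $-\infty$ outside the support.

## Sampling and diagnostics

The posterior is explored by single-site adaptive random-walk
Metropolis-within-Gibbs (compiled in C++, driven by R's RNG so runs are
reproducible under a seed). Proposal scales adapt in batches of 50
iterations toward an acceptance rate of 0.44 -- the optimal rate for
one-dimensional Gaussian targets -- during burn-in only, and are frozen
afterwards, which preserves the stationary distribution of the post-burn-in
chain. Chains start from per-subject least-squares fits (a grid over
$R \in \{0.1, \dots, 0.9\}$ with closed-form $I, C$ given $R$), jittered per
chain; hyperparameters start at group-wise moments of these fits. The
hierarchy makes the fit robust to these starting values, but starting in the
typical set shortens burn-in.

`summarize_fit()` reports posterior means, SDs, central 95% intervals, a
split-chain potential scale reduction $\widehat R$ (the larger of the
classical and the rank-normalized statistic, so both location shifts and
heavy-tail pathologies are flagged) and a rank-normalized effective sample
size with Geyer's initial-monotone-sequence truncation. Default settings --
2 chains of 4000 iterations, 1000 burn-in -- give $\widehat R \le 1.06$ and
several hundred effective draws for every group-level mean on cohorts of the
default size; per-subject point estimates (posterior means) feed the
factorial analyses.

Two independent oracles guard the sampler in the test suite: with $R$ fixed
and flat priors the model is linear-Gaussian and the posterior is known in
closed form, and on a single subject the full nonlinear posterior is
computed by 3-D grid quadrature. Both must agree with the MCMC output within
Monte-Carlo error.

## Consolidation scores and their statistics

The consolidation score is the mean of the three retest trials minus the
mean of three training trials -- the last three by index (primary) or the
best three by value (the fatigue control, which guards against end-of-session
performance drops inflating the overnight gain). Because raw gain scores are
positively skewed, the factorial analysis uses a square-root transform;
for scores that can be negative the package uses the **signed** root
$\operatorname{sign}(x)\sqrt{|x|}$, which is monotone and defined everywhere
(a shift-then-root variant is available by flag).

`factorial_anova()` fits all main effects and two-way interactions (the
model implied by a 128-subject cohort with denominator df 117) by effect-coded
least squares and reports partial (Type-III-style) sums of squares: on
balanced data this is exactly the classical order-invariant decomposition,
and it is the convention that degrades gracefully to the unbalanced
recruitment of the 30-minute control cohort (20/20/14/13). Notably, those
group sizes sum to 67 subjects, and the two-way-interaction model then has
residual df $67 - 11 = 56$ -- matching the $F_{1,56}$ form such designs
report. Simple effects test one factor within each level of another using
the contrast of unweighted cell means against the pooled residual mean
square of the full model, so their denominator df equal the full model's
residual df; per-level Welch tests are a non-default option. One-sample
t-tests and Pearson correlations wrap the standard R tests; the comparison
of two independent correlations uses Fisher's r-to-z,
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$, with the one-tailed p taken in the direction
of the observed difference. No multiple-testing correction is applied.

## What the synthetic generator emulates

`scenario_cohort()` produces cohorts with fully recorded ground truth:

* **main** -- 128 subjects, 8 per cell of the 2x2x2x2 design (piano
  experience, dichotomized age with 30 belonging to "older", intelligence
  group, gender); 12 + 3 trials; players are generated with higher initial
  performance and faster learning (lower $R$), the high-intelligence group
  with higher initial performance only. The mean overnight gain is 3
  sequences/trial except for older non-players, who sit 2 lower -- prior
  piano experience compensates the age-related decline without helping the
  young. Subject-level gain noise has SD 2; trial noise SD 1.
* **control1** -- the unbalanced 30-minute-delay recruitment
  (20/20/14/13); age lowers the gain, piano does not.
* **control2** -- 67 young subjects, 6 training trials, both delays, no
  factor effects on the gain.
* **null** -- as main with every factor effect (gain and curve) removed.

Day-2 trials are generated as plateau $I + C$ plus the subject's realized
gain plus noise. One consequence: the noise-free consolidation score equals
the configured gain plus the small analytic curve-tail deficit
$C \cdot \overline{R^{\,t-1}}$ over the last three training trials (about
0.02 sequences/trial at the default parameters) -- the tests assert this
identity exactly. All randomness flows from one master seed through an
avalanche-quality integer hash to per-subject substreams, so cohorts are
bit-reproducible and a subject's data depend only on the seed and its index.

The generator does **not** emulate keypress-level timing, errors within
sequences, rest periods, learning during the retest, floor/ceiling effects,
dropout, or any parametric (continuous) dependence of the gain on age within
the bands -- the configured cell means are constant within each design cell.
Passing tests therefore demonstrate that the statistical machinery recovers
what this generative family encodes, not that real tapping data satisfy the
model's assumptions.

## Numerical choices and degenerate inputs

* Truncated draws (subject parameters, $R$ into $(0,1)$, $I, C \ge 0$) use
  rejection sampling; a zero-SD group returns its mean exactly.
* Trial values are clipped at zero after noise; with the default parameters
  clipping is rare (plateaus sit far from zero).
* Constant responses yield zero effect SS (and undefined F) rather than an
  error; rank-deficient designs raise an error naming the aliased effects.
* Zero-variance inputs to t-tests and correlations raise degenerate-input
  errors instead of returning NaN.
* The ESS estimate is clamped below by $1/m$ pair sums to guard antithetic
  chains; zero-variance (fixed) parameters report NA diagnostics.

## Problem sizes of the shipped checks

The package's acceptance checks run, per seed: the exact worked examples
(Fisher z, df reconstruction, cohort counts); 100 random balanced designs
against a brute-force cell-mean-projection ANOVA oracle; one
conjugate-limit MCMC comparison (4 subjects, 2 x 21k draws); 20 simulated
main cohorts for hyperparameter coverage (960 intervals) and subject-level
recovery; 500 null-scenario replicates for the 5% type-I band on all ten
effects; 200 main-scenario replicates for the power of the piano-by-age
interaction and its sign pattern; and 200 shifted-gamma replicates for the
skewness-reduction property of the signed root. These sizes keep each
property statistically meaningful (binomial bands of a point or two) while
the full suite completes in minutes on a single CPU.

## Known limitations

* The sampler is single-site random walk: adequate at these dimensions, but
  no gradient information, so very low observation noise (which tightens
  per-subject posteriors sharply) lengthens burn-in.
* The "MANOVA" over curve parameters is realized as univariate ANOVAs per
  parameter ($I$, $R$, and the implied day-1 improvement
  $C(1 - R^{\,n-1})$); no multivariate statistic is computed.
* Group-level SDs are weakly identified with 8 subjects per cell; their
  intervals are wide, and coverage claims in the tests concern the group
  means.
* The XLSX supplements of the original control experiments have no
  documented layout; the readers accept only the package's CSV schemas.
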