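make_state <- function(I, C, R, ids = paste0("S", seq_along(I)),
                       groups = "g1", mu = NULL, sigma = NULL,
                       sigma_obs = c(g1 = 1)) {
  list(I = setNames(I, ids), C = setNames(C, ids), R = setNames(R, ids),
       mu = mu, sigma = sigma, groups = groups, sigma_obs = sigma_obs)
}

test_that("learning curve follows the power law and validates t", {
  expect_equal(learning_curve(5, 10, 0.5, 1), 5)
  expect_equal(learning_curve(5, 10, 0.5, 3), 12.5)
  y <- learning_curve(2, 8, 0.9, 1:200)
  expect_true(all(diff(y) > 0))
  expect_lt(10 - y[200], 1e-8)
  expect_error(learning_curve(5, 10, 0.5, 0), "integer")
  expect_error(learning_curve(5, 10, 0.5, 1.5), "integer")
})

test_that("log density reproduces hand-computable cases", {
  # one observation exactly on the curve, sd 1, flat prior: -log(sqrt(2*pi))
  dat <- data.frame(subject_id = "S1", session = "day1", trial = 1,
                    correct_sequences = 5)
  st <- make_state(5, 10, 0.5)
  lp <- log_density(st, dat, c(S1 = "g1"), curve_priors(flat = TRUE))
  expect_equal(lp, -0.5 * log(2 * pi))

  # R outside the unit interval is impossible
  st_bad <- make_state(5, 10, 1.2)
  expect_equal(log_density(st_bad, dat, c(S1 = "g1"),
                           curve_priors(flat = TRUE)), -Inf)

  # doubling the data doubles the (flat-prior) density exactly
  co <- scenario_cohort("main", seed = 2)
  d1 <- co$trials[co$trials$session == "day1", ][1:24, ]
  ids <- unique(d1$subject_id)
  tru <- co$truth$subject_params
  k <- match(ids, tru$subject_id)
  st2 <- make_state(tru$I[k], tru$C[k], tru$R[k], ids = ids,
                    sigma_obs = c(g1 = 1.3))
  grouping <- setNames(rep("g1", 2), ids)
  lp1 <- log_density(st2, d1, grouping, curve_priors(flat = TRUE))
  doubled <- rbind(d1, d1)
  lp2 <- log_density(st2, doubled, grouping, curve_priors(flat = TRUE))
  expect_equal(lp2, 2 * lp1)
})

test_that("log density is additive over independent subjects", {
  mkdat <- function(id, y) data.frame(subject_id = id, session = "day1",
                                      trial = seq_along(y),
                                      correct_sequences = y)
  y1 <- learning_curve(5, 10, 0.5, 1:6) + 0.3
  y2 <- learning_curve(7, 6, 0.3, 1:6) - 0.2
  hy <- list(mu = data.frame(I = c(5, 7), C = c(10, 6), R = c(0.5, 0.3)),
             sigma = data.frame(I = c(1, 2), C = c(1, 2), R = c(0.1, 0.1)))
  st_a <- make_state(5.1, 9.9, 0.52, ids = "A", groups = "gA",
                     mu = hy$mu[1, ], sigma = hy$sigma[1, ],
                     sigma_obs = c(gA = 1))
  st_b <- make_state(7.1, 6.1, 0.31, ids = "B", groups = "gB",
                     mu = hy$mu[2, ], sigma = hy$sigma[2, ],
                     sigma_obs = c(gB = 2))
  st_ab <- list(I = c(A = 5.1, B = 7.1), C = c(A = 9.9, B = 6.1),
                R = c(A = 0.52, B = 0.31), mu = hy$mu, sigma = hy$sigma,
                groups = c("gA", "gB"), sigma_obs = c(gA = 1, gB = 2))
  lp_a <- log_density(st_a, mkdat("A", y1), c(A = "gA"))
  lp_b <- log_density(st_b, mkdat("B", y2), c(B = "gB"))
  lp_ab <- log_density(st_ab, rbind(mkdat("A", y1), mkdat("B", y2)),
                       c(A = "gA", B = "gB"))
  expect_equal(lp_ab, lp_a + lp_b)
})

test_that("sampler matches the closed-form posterior when the model is linear", {
  # R fixed at truth, flat priors, known observation SD: the model is linear
  # in (I, C) and the posterior is ordinary linear-Gaussian regression
  set.seed(4)
  R_true <- c(0.5, 0.35, 0.6, 0.45)
  I_true <- c(5, 8, 6, 10); C_true <- c(10, 7, 9, 6)
  sobs <- 1.5
  trials <- do.call(rbind, lapply(1:4, function(s) {
    data.frame(subject_id = paste0("S", s), session = "day1", trial = 1:12,
               correct_sequences = learning_curve(I_true[s], C_true[s],
                                                  R_true[s], 1:12) +
                 rnorm(12, 0, sobs))
  }))
  grouping <- setNames(rep("g", 4), paste0("S", 1:4))
  cfg <- mcmc_config(n_chains = 2, n_iter = 9000, n_burnin = 1000,
                     seed = 99, priors = curve_priors(flat = TRUE),
                     fixed_R = R_true, fixed_sigma_obs = sobs)
  fit <- mcmc_fit(trials, grouping, cfg)
  sm <- summarize_fit(fit)$summary
  for (s in 1:4) {
    d <- trials[trials$subject_id == paste0("S", s), ]
    post <- oracle_linear_posterior(d$trial, d$correct_sequences,
                                    R_true[s], sobs)
    for (k in 1:2) {
      par <- sprintf("%s[S%d]", c("I", "C")[k], s)
      row <- sm[sm$parameter == par, ]
      mcse <- row$sd / sqrt(row$ess)
      expect_lt(abs(row$mean - post$mean[k]), 3 * mcse + 1e-8)
      expect_lt(abs(row$sd - post$sd[k]) / post$sd[k], 0.1)
    }
    # fixed R is passed through untouched
    expect_equal(sm$mean[sm$parameter == sprintf("R[S%d]", s)], R_true[s])
  }
})

test_that("sampler posterior matches grid quadrature on one subject", {
  # independent oracle: 3-D grid integration of the unnormalized posterior
  # (flat priors, known sd), written directly from the likelihood formula
  set.seed(8)
  y <- learning_curve(6, 9, 0.5, 1:12) + rnorm(12, 0, 0.8)
  trials <- data.frame(subject_id = "S1", session = "day1", trial = 1:12,
                       correct_sequences = y)
  Ig <- seq(3, 9, length.out = 60)
  Cg <- seq(5, 13, length.out = 60)
  Rg <- seq(0.2, 0.8, length.out = 60)
  grid <- expand.grid(I = Ig, C = Cg, R = Rg)
  ll <- vapply(seq_len(nrow(grid)), function(i) {
    mu <- grid$I[i] + grid$C[i] * (1 - grid$R[i]^(0:11))
    -sum((y - mu)^2) / (2 * 0.8^2)
  }, 0)
  w <- exp(ll - max(ll)); w <- w / sum(w)
  post_mean <- c(sum(w * grid$I), sum(w * grid$C), sum(w * grid$R))

  cfg <- mcmc_config(n_chains = 2, n_iter = 11000, n_burnin = 1000,
                     thin = 2, seed = 5,
                     priors = curve_priors(flat = TRUE),
                     fixed_sigma_obs = 0.8)
  fit <- mcmc_fit(trials, c(S1 = "g"), cfg)
  sm <- summarize_fit(fit)$summary
  for (k in seq_along(c("I", "C", "R"))) {
    row <- sm[sm$parameter == sprintf("%s[S1]", c("I", "C", "R")[k]), ]
    mcse <- row$sd / sqrt(row$ess)
    expect_lt(abs(row$mean - post_mean[k]), 4 * mcse + 0.02)
  }
})

test_that("hierarchical fit recovers parameters from low-noise data", {
  hy <- group_hypers(data.frame(cell = "g"), mu_I = 10, mu_C = 8,
                     mu_R = 0.5, sigma_I = 2, sigma_C = 1.5, sigma_R = 0.08,
                     sigma_obs = 0.01)
  trials <- do.call(rbind, lapply(1:8, function(s) {
    p <- draw_subject_params(hy, "g", seed = 100 + s)
    data.frame(subject_id = sprintf("S%d", s), session = "day1", trial = 1:12,
               correct_sequences = simulate_day1(p, 12, 0.01,
                                                 seed = 200 + s),
               I_true = p$I)
  }))
  grouping <- setNames(rep("g", 8), sprintf("S%d", 1:8))
  fit <- mcmc_fit(trials[, 1:4], grouping,
                  mcmc_config(n_chains = 2, n_iter = 4000, n_burnin = 1000,
                              seed = 31))
  est <- summarize_fit(fit)$estimates
  truth <- unique(trials[c("subject_id", "I_true")])
  expect_true(all(abs(est$I - truth$I_true) < 0.2))
})

test_that("retained draws respect supports and config validation works", {
  co <- scenario_cohort("main", seed = 13)
  sub <- co$factors$subject_id[1:16]
  trials <- co$trials[co$trials$subject_id %in% sub, ]
  grouping <- fit_grouping(co$factors[1:16, ], by = c("piano"))
  fit <- mcmc_fit(trials, grouping,
                  mcmc_config(n_chains = 2, n_iter = 600, n_burnin = 200,
                              seed = 3))
  R_cols <- grepl("^R\\[", fit$params)
  expect_true(all(fit$draws[, R_cols, ] > 0 & fit$draws[, R_cols, ] < 1))
  sig_cols <- grepl("^sigma", fit$params)
  expect_true(all(fit$draws[, sig_cols, ] > 0))

  expect_error(mcmc_config(n_iter = 100, n_burnin = 100), "n_iter")
  expect_error(mcmc_config(n_chains = 1), "n_chains")
  two_trials <- trials[trials$trial <= 2 | trials$session == "day2", ]
  expect_error(mcmc_fit(two_trials, grouping), ">= 3 day-1 trials")
})

test_that("identical seed and config give identical draws", {
  co <- scenario_cohort("main", seed = 17)
  sub <- co$factors$subject_id[1:8]
  trials <- co$trials[co$trials$subject_id %in% sub, ]
  grouping <- setNames(rep("g", 8), sub)
  cfg <- mcmc_config(n_chains = 2, n_iter = 500, n_burnin = 100, seed = 77)
  f1 <- mcmc_fit(trials, grouping, cfg)
  f2 <- mcmc_fit(trials, grouping, cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- mcmc_fit(trials, grouping,
                 mcmc_config(n_chains = 2, n_iter = 500, n_burnin = 100,
                             seed = 78))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("convergence diagnostics behave like the standard estimators", {
  set.seed(10)
  iid <- matrix(rnorm(2e4), ncol = 2)
  expect_gte(rhat(iid), 1 - 1e-6)
  expect_lt(rhat(iid), 1.05)
  expect_gt(ess(iid), 0.5 * length(iid))
  far <- cbind(rnorm(500, 0), rnorm(500, 100))
  expect_gt(rhat(far), 2)

  const <- matrix(7, 200, 2)
  expect_true(is.na(rhat(const)))
})

test_that("summaries report means, intervals and point estimates", {
  co <- scenario_cohort("main", seed = 19)
  sub <- co$factors$subject_id[1:8]
  trials <- co$trials[co$trials$subject_id %in% sub, ]
  grouping <- setNames(rep("g", 8), sub)
  fit <- mcmc_fit(trials, grouping,
                  mcmc_config(n_chains = 2, n_iter = 1200, n_burnin = 200,
                              seed = 7))
  sm <- summarize_fit(fit)
  expect_true(all(sm$summary$q2.5 <= sm$summary$mean + 1e-12))
  expect_true(all(sm$summary$q97.5 >= sm$summary$mean - 1e-12))
  expect_true(all(sm$summary$rhat >= 1 - 1e-6, na.rm = TRUE))
  expect_setequal(sm$estimates$subject_id, sub)
  expect_true(all(sm$estimates$R > 0 & sm$estimates$R < 1))

  short <- fit
  short$draws <- fit$draws[1:50, , , drop = FALSE]
  expect_error(summarize_fit(short), ">= 100 retained draws")
})
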