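#' MCMC configuration for the hierarchical curve fit
#'
#' @param n_chains number of independent chains (>= 2).
#' @param n_iter total iterations per chain (> `n_burnin`).
#' @param n_burnin burn-in iterations discarded from each chain (>= 0);
#'   proposal-scale adaptation runs only here and is frozen afterwards.
#' @param thin keep every `thin`-th post-burn-in draw (>= 1).
#' @param seed integer seed; each chain runs on a deterministic substream.
#' @param adapt_batch adaptation window (iterations per scale update).
#' @param priors a [curve_priors()] list.
#' @param fixed_R optional numeric: fix every subject's R at these values
#'   (recycled over subjects); R is then not sampled.
#' @param fixed_sigma_obs optional positive scalar: fix the observation SD of
#'   every group (not sampled).
#' @param init_jitter SD of the random perturbation of the starting values,
#'   applied per chain so chains start from distinct points.
#' @return list of settings, class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, n_iter = 4000L, n_burnin = 1000L,
                        thin = 1L, seed = 1L, adapt_batch = 50L,
                        priors = curve_priors(), fixed_R = NULL,
                        fixed_sigma_obs = NULL, init_jitter = 0.1) {
  if (n_chains < 2) stop_arg("n_chains must be >= 2")
  if (!(n_iter > n_burnin && n_burnin >= 0))
    stop_arg("need n_iter > n_burnin >= 0")
  if (thin < 1) stop_arg("thin must be >= 1")
  if ((n_iter - n_burnin) %/% thin < 1)
    stop_arg("no draws would be retained")
  if (!is.null(fixed_sigma_obs) && fixed_sigma_obs <= 0)
    stop_arg("fixed_sigma_obs must be positive")
  if (!is.null(fixed_R) && any(fixed_R <= 0 | fixed_R >= 1))
    stop_arg("fixed_R values must lie in (0, 1)")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), adapt_batch = as.integer(adapt_batch),
                 priors = priors, fixed_R = fixed_R,
                 fixed_sigma_obs = fixed_sigma_obs,
                 init_jitter = init_jitter),
            class = "mcmc_config")
}

# least-squares starting values: grid over R with closed-form (I, C) given R
init_curve_params <- function(t, y, R_grid = seq(0.1, 0.9, by = 0.1)) {
  best <- NULL
  for (R in R_grid) {
    X <- cbind(1, 1 - R^(t - 1))
    fit <- stats::lm.fit(X, y)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(I = fit$coefficients[[1]], C = fit$coefficients[[2]],
                   R = R, sse = sse,
                   sigma = sqrt(sse / max(1, length(y) - 2)))
  }
  best
}

#' Fit the hierarchical learning-curve model by MCMC
#'
#' Runs `n_chains` independent adaptive Metropolis-within-Gibbs chains
#' targeting [log_density()]. Starting values come from per-subject
#' least-squares fits (grid over R with closed-form I and C), with
#' hyperparameters initialized at group-wise moments of those fits; each
#' chain perturbs the start by `init_jitter`.
#'
#' @param trials trial table (long form); only the `day1` session is used.
#' @param grouping named character vector subject_id -> group label (see
#'   [fit_grouping()]).
#' @param config an [mcmc_config()].
#' @return object of class `taplearn_fit`: list with `draws` (array of
#'   retained draws, iterations x parameters x chains), `params` (parameter
#'   name registry), `subjects`, `groups`, `grouping`, `n_train`, `config`
#'   and the initial values.
#' @export
mcmc_fit <- function(trials, grouping, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  day1 <- trials[trials$session == "day1", , drop = FALSE]
  subjects <- unique(day1$subject_id)
  S <- length(subjects)
  if (!all(subjects %in% names(grouping)))
    stop_arg("grouping lacks entries for some subjects in the data")
  n_per <- table(day1$subject_id)
  if (any(n_per < 3))
    stop_arg("every subject needs >= 3 day-1 trials; offending: %s",
             paste(names(n_per)[n_per < 3], collapse = ", "))
  glab <- unique(unname(grouping[subjects]))
  gidx <- match(unname(grouping[subjects]), glab)
  G <- length(glab)
  flat <- isTRUE(config$priors$flat)
  if (!flat && any(table(gidx) < 2))
    stop_arg("every hyperparameter group needs >= 2 subjects")

  # order observations subject-by-subject for the sampler
  day1 <- day1[order(match(day1$subject_id, subjects), day1$trial), ]
  off <- c(0L, cumsum(as.integer(table(match(day1$subject_id, subjects)))))

  inits <- lapply(subjects, function(s) {
    rows <- day1$subject_id == s
    init_curve_params(day1$trial[rows], day1$correct_sequences[rows])
  })
  I0 <- vapply(inits, `[[`, 0, "I")
  C0 <- vapply(inits, `[[`, 0, "C")
  R0 <- pmin(0.95, pmax(0.05, vapply(inits, `[[`, 0, "R")))
  s0 <- vapply(inits, `[[`, 0, "sigma")
  if (!is.null(config$fixed_R)) R0 <- rep_len(config$fixed_R, S)

  mom <- function(x, idx, floor_sd) {
    m <- tapply(x, idx, mean)
    s <- pmax(floor_sd, tapply(x, idx, stats::sd), na.rm = TRUE)
    s[is.na(s)] <- floor_sd
    cbind(mean = as.numeric(m), sd = as.numeric(s))
  }
  mI <- mom(I0, gidx, 0.1); mC <- mom(C0, gidx, 0.1); mR <- mom(R0, gidx, 0.02)
  mu0 <- cbind(mI[, 1], mC[, 1], pmin(0.95, pmax(0.05, mR[, 1])))
  sig0 <- cbind(mI[, 2], mC[, 2], mR[, 2])
  sobs0 <- pmax(0.05, as.numeric(tapply(s0, gidx, stats::median)))
  if (!is.null(config$fixed_sigma_obs))
    sobs0 <- rep(config$fixed_sigma_obs, G)

  params <- c(sprintf("I[%s]", subjects), sprintf("C[%s]", subjects),
              sprintf("R[%s]", subjects),
              sprintf("mu_I[%s]", glab), sprintf("mu_C[%s]", glab),
              sprintf("mu_R[%s]", glab),
              sprintf("sigma_I[%s]", glab), sprintf("sigma_C[%s]", glab),
              sprintf("sigma_R[%s]", glab), sprintf("sigma_obs[%s]", glab))
  n_keep <- (config$n_iter - config$n_burnin) %/% config$thin
  draws <- array(NA_real_, dim = c(n_keep, length(params), config$n_chains),
                 dimnames = list(NULL, params, NULL))

  for (ch in seq_len(config$n_chains)) {
    res <- with_seed(substream_seed(config$seed, ch), {
      jit <- function(x, sd) x + stats::rnorm(length(x), 0, sd)
      Ij <- jit(I0, config$init_jitter)
      Cj <- jit(C0, config$init_jitter)
      Rj <- if (is.null(config$fixed_R))
        pmin(0.98, pmax(0.02, jit(R0, config$init_jitter / 2))) else R0
      muj <- if (flat) mu0 else
        cbind(jit(mu0[, 1], config$init_jitter),
              jit(mu0[, 2], config$init_jitter),
              pmin(0.95, pmax(0.05, jit(mu0[, 3], config$init_jitter / 5))))
      mwg_sample(day1$correct_sequences, as.integer(day1$trial),
                 as.integer(off), as.integer(gidx - 1L), G,
                 Ij, Cj, stats::qlogis(Rj),
                 muj, sig0, sobs0,
                 config$n_iter, config$n_burnin, config$thin,
                 config$adapt_batch,
                 config$priors$mu_sd, config$priors$sigma_scale,
                 flat, !is.null(config$fixed_R),
                 !is.null(config$fixed_sigma_obs))
    })
    draws[, , ch] <- res$draws
  }

  structure(list(draws = draws, params = params, subjects = subjects,
                 groups = glab, grouping = grouping[subjects],
                 n_train = max(day1$trial), config = config,
                 init = list(I = I0, C = C0, R = R0, mu = mu0, sigma = sig0,
                             sigma_obs = sobs0)),
            class = "taplearn_fit")
}

#' @export
print.taplearn_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical learning-curve fit: %d subjects, %d groups, %d chains x %d draws\n",
    length(x$subjects), length(x$groups), dim(x$draws)[3], dim(x$draws)[1]))
  invisible(x)
}
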