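# Independent oracles used by the tests. These never call the package's own
# implementations of the quantities they check.

# Brute-force factorial sums of squares for *balanced* designs, via
# inclusion-exclusion over marginal cell means: the effect estimate of a
# term S at each observation is sum_{T subset of S} (-1)^{|S|-|T|} mean_T,
# and its SS is the sum of squared estimates.
oracle_anova_ss <- function(response, subjects, factor_names,
                            interaction_order = 2L) {
  n <- length(response)
  grand <- mean(response)
  terms <- unlist(lapply(seq_len(interaction_order), function(k)
    utils::combn(factor_names, k, simplify = FALSE)), recursive = FALSE)
  marginal_mean <- function(cols) {
    if (!length(cols)) return(rep(grand, n))
    key <- do.call(interaction, c(unname(subjects[cols]), drop = TRUE))
    stats::ave(response, key, FUN = mean)
  }
  ss <- vapply(terms, function(S) {
    est <- rep(0, n)
    for (k in 0:length(S)) {
      subsets <- if (k == 0) list(character(0)) else
        utils::combn(S, k, simplify = FALSE)
      for (T in subsets)
        est <- est + (-1)^(length(S) - k) * marginal_mean(T)
    }
    sum(est^2)
  }, 0)
  names(ss) <- vapply(terms, paste, "", collapse = ":")
  ss
}

oracle_anova_F <- function(response, subjects, factor_names,
                           interaction_order = 2L) {
  ss <- oracle_anova_ss(response, subjects, factor_names, interaction_order)
  ss_tot <- sum((response - mean(response))^2)
  ss_res <- ss_tot - sum(ss)
  df_model <- length(ss) # binary factors: 1 df per term
  df_res <- length(response) - 1 - df_model
  list(ss = ss, ss_res = ss_res, df_res = df_res,
       F = ss / (ss_res / df_res))
}

# a random balanced two-level design with at most `max_n` subjects and a
# positive residual df under the two-way-interaction model
random_balanced_design <- function(max_n = 32) {
  k <- sample(2:4, 1)
  npc_max <- max_n %/% 2^k
  npc <- sample(2:max(2, npc_max), 1)
  factors <- lapply(seq_len(k), function(i)
    factor_spec(paste0("f", i), c("lo", "hi")))
  subjects <- generate_design(npc, factors, seed = sample.int(1e6, 1))
  response <- rnorm(nrow(subjects)) +
    2 * (subjects$f1 == "hi") + (subjects$f2 == "hi") +
    0.5 * (subjects$f1 == "hi") * (subjects$f2 == "hi")
  list(subjects = subjects, response = response,
       factor_names = paste0("f", seq_len(k)))
}

# closed-form posterior of (I, C) for one subject with R fixed, flat priors
# and known observation SD: ordinary linear-Gaussian regression
oracle_linear_posterior <- function(t, y, R, sigma_obs) {
  X <- cbind(1, 1 - R^(t - 1))
  XtX_inv <- solve(crossprod(X))
  beta <- XtX_inv %*% crossprod(X, y)
  covb <- sigma_obs^2 * XtX_inv
  list(mean = as.numeric(beta), sd = sqrt(diag(covb)))
}

# a minimal deterministic trial table for two subjects
toy_trials <- function(I = c(5, 6), C = c(10, 8), R = c(0.5, 0.4),
                       n_train = 12) {
  do.call(rbind, lapply(seq_along(I), function(s) {
    rbind(
      data.frame(subject_id = paste0("S", s), session = "day1",
                 trial = 1:n_train,
                 correct_sequences = learning_curve(I[s], C[s], R[s],
                                                    1:n_train)),
      data.frame(subject_id = paste0("S", s), session = "day2", trial = 1:3,
                 correct_sequences = rep(I[s] + C[s], 3)))
  }))
}
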