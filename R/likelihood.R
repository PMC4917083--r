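#' Map subjects to hyperparameter groups
#'
#' The hierarchy estimates separate (mu, sigma) hyperparameters per group of
#' subjects; by default every design cell is its own group, but the grouping
#' can be coarsened (e.g. to the four piano x age groups) via `by`.
#'
#' @param subjects subject-factor data frame.
#' @param by character vector of factor columns defining the groups.
#' @return named character vector: subject_id -> group label.
#' @export
fit_grouping <- function(subjects,
                         by = c("piano", "age_group", "intelligence",
                                "gender")) {
  by <- intersect(by, names(subjects))
  if (!length(by)) stop_arg("no grouping columns found in subject table")
  g <- do.call(paste, c(unname(subjects[by]), sep = "|"))
  stats::setNames(g, subjects$subject_id)
}

#' Prior specification for the hierarchical curve model
#'
#' Weakly informative on the scale of finger-tapping performance (at most a
#' few tens of sequences per 30 s trial): group means of I and C are
#' Normal(0, 10^2), the group mean of R is Uniform(0, 1), and all standard
#' deviations (subject-level and observation) are Half-Normal(0, 5^2).
#' With `flat = TRUE` the subject-level hierarchy and all hyperpriors are
#' dropped (improper flat priors on I and C, flat on R over (0, 1)); used for
#' closed-form cross-checks.
#'
#' @param mu_sd prior SD of the I and C group means.
#' @param sigma_scale scale of the half-normal prior on all SDs.
#' @param flat drop hierarchy and hyperpriors.
#' @return list of prior settings.
#' @export
curve_priors <- function(mu_sd = 10, sigma_scale = 5, flat = FALSE) {
  stopifnot(mu_sd > 0, sigma_scale > 0)
  list(mu_sd = mu_sd, sigma_scale = sigma_scale, flat = isTRUE(flat))
}

half_normal_lpdf <- function(x, scale) {
  ifelse(x > 0,
         log(2) - log(scale) - 0.5 * log(2 * pi) - x^2 / (2 * scale^2),
         -Inf)
}

#' Log posterior density of the hierarchical curve model (up to a constant)
#'
#' Reference (pure R) implementation of the model's unnormalized log
#' posterior: the sum of (a) the Normal log-likelihood of every day-1
#' observation around its subject's curve value with the group's observation
#' SD, (b) the Normal log-density of each subject parameter around its
#' group's (mu, sigma), and (c) the hyperpriors of [curve_priors()]. Returns
#' `-Inf` whenever any R is outside (0, 1) or any SD is non-positive. The
#' compiled sampler targets exactly this density (over (I, C, R); its
#' internal logit parameterization of R carries the matching Jacobian).
#'
#' @param state list with numeric vectors `I`, `C`, `R` named by subject, and
#'   (unless `priors$flat`) data frames/lists `mu` and `sigma` with columns
#'   `I`, `C`, `R` (rows = groups, rownames or `group` column = labels) and a
#'   named numeric `sigma_obs` per group. With `priors$flat`, `sigma_obs`
#'   is still required (fixed observation SD).
#' @param data trial table restricted to (or containing) the `day1` session.
#' @param grouping named character vector subject_id -> group label.
#' @param priors a [curve_priors()] list.
#' @return scalar log density (may be `-Inf`).
#' @export
log_density <- function(state, data, grouping, priors = curve_priors()) {
  day1 <- data[data$session == "day1", , drop = FALSE]
  subjects <- names(state$I)
  if (is.null(subjects) || !setequal(subjects, unique(day1$subject_id)))
    stop_arg("state subjects do not match the day-1 data")
  if (!all(subjects %in% names(grouping)))
    stop_arg("grouping is missing subjects present in the state")
  if (length(state$C) != length(state$I) ||
      length(state$R) != length(state$I))
    stop_arg("state parameter vectors have mismatched lengths")

  if (any(state$R <= 0 | state$R >= 1)) return(-Inf)

  groups <- unique(unname(grouping[subjects]))
  sobs <- state$sigma_obs
  if (any(sobs <= 0)) return(-Inf)
  if (!all(groups %in% names(sobs)))
    stop_arg("sigma_obs is missing entries for some groups")

  lp <- 0
  # (a) observation likelihood
  for (s in subjects) {
    rows <- day1$subject_id == s
    mu <- learning_curve(state$I[s], state$C[s], state$R[s], day1$trial[rows])
    lp <- lp + sum(stats::dnorm(day1$correct_sequences[rows], mu,
                                sobs[[grouping[[s]]]], log = TRUE))
  }
  if (priors$flat) {
    # flat on I, C and on R over (0, 1); no hierarchy, no hyperpriors
    return(lp)
  }

  mu <- as.data.frame(state$mu)
  sg <- as.data.frame(state$sigma)
  glab <- state$groups %||% rownames(mu)
  if (is.null(glab) || !all(groups %in% glab))
    stop_arg("hyperparameter rows do not cover all groups")
  if (any(sg$I <= 0 | sg$C <= 0 | sg$R <= 0)) return(-Inf)

  # (b) subject-level hierarchy
  for (s in subjects) {
    g <- match(grouping[[s]], glab)
    lp <- lp + stats::dnorm(state$I[s], mu$I[g], sg$I[g], log = TRUE) +
      stats::dnorm(state$C[s], mu$C[g], sg$C[g], log = TRUE) +
      stats::dnorm(state$R[s], mu$R[g], sg$R[g], log = TRUE)
  }
  # (c) hyperpriors, counted once per group present in the data
  for (g in match(groups, glab)) {
    if (mu$R[g] <= 0 || mu$R[g] >= 1) return(-Inf)
    lp <- lp + stats::dnorm(mu$I[g], 0, priors$mu_sd, log = TRUE) +
      stats::dnorm(mu$C[g], 0, priors$mu_sd, log = TRUE) +
      sum(half_normal_lpdf(c(sg$I[g], sg$C[g], sg$R[g],
                             sobs[[glab[g]]]), priors$sigma_scale))
  }
  lp
}
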