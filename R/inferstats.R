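#' Signed square-root transform
#'
#' `sign(x) * sqrt(|x|)`: monotone, defined for negative scores, and
#' variance-stabilizing for positively skewed gain scores.
#'
#' @param x numeric vector.
#' @return transformed vector.
#' @export
signed_sqrt <- function(x) sign(x) * sqrt(abs(x))

#' Offline consolidation score of one subject
#'
#' Mean of the three retest (day-2) trials minus the mean of three training
#' (day-1) trials: the last three by trial index (`"last3"`, the primary
#' measure) or the best three by value (`"best3"`, the fatigue-control
#' variant). The transformed score is the signed square root of the raw
#' score; `transform = "shift_root"` instead shifts all scores above zero by
#' the caller-supplied `shift` before the root.
#'
#' @param day1 numeric day-1 trial values in trial-index order (>= 3).
#' @param day2 numeric day-2 trial values (exactly 3).
#' @param mode `"last3"` or `"best3"`.
#' @param transform `"signed_root"` (default) or `"shift_root"`.
#' @param shift shift used by `"shift_root"`.
#' @return list with `raw`, `transformed`, `mode`.
#' @export
#' @examples
#' consolidation_score(c(8, 9, 10, 11, 12), c(13, 14, 15))$raw # 3
consolidation_score <- function(day1, day2, mode = c("last3", "best3"),
                                transform = c("signed_root", "shift_root"),
                                shift = 0) {
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  if (length(day1) < 3) stop_arg("day1 must contain at least 3 trials")
  if (length(day2) != 3) stop_arg("day2 must contain exactly 3 trials")
  sel <- if (mode == "last3") utils::tail(day1, 3) else
    sort(day1, decreasing = TRUE)[1:3]
  raw <- mean(day2) - mean(sel)
  transformed <- if (transform == "signed_root") signed_sqrt(raw) else {
    if (raw + shift < 0)
      stop_arg("shift_root needs raw + shift >= 0 (raw = %g)", raw)
    sqrt(raw + shift)
  }
  list(raw = raw, transformed = transformed, mode = mode)
}

#' Consolidation scores for every subject of a trial table
#'
#' @param trials long trial table with `day1`/`day2` sessions.
#' @param mode,transform,shift passed to [consolidation_score()].
#' @return data frame: `subject_id`, `raw`, `transformed`, plus the mean
#'   day-1 performance (`day1_mean`) used by the correlation panel.
#' @export
score_table <- function(trials, mode = "last3", transform = "signed_root",
                        shift = 0) {
  subjects <- unique(trials$subject_id)
  out <- lapply(subjects, function(s) {
    d1 <- trials[trials$subject_id == s & trials$session == "day1", ]
    d2 <- trials[trials$subject_id == s & trials$session == "day2", ]
    d1 <- d1$correct_sequences[order(d1$trial)]
    d2 <- d2$correct_sequences[order(d2$trial)]
    sc <- consolidation_score(d1, d2, mode, transform, shift)
    data.frame(subject_id = s, raw = sc$raw, transformed = sc$transformed,
               day1_mean = mean(d1), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# factorial ANOVA

as_effect_factors <- function(subjects, factor_names) {
  missing <- setdiff(factor_names, names(subjects))
  if (length(missing))
    stop_arg("subject table lacks factor column(s): %s",
             paste(missing, collapse = ", "))
  out <- subjects[factor_names]
  for (nm in factor_names) {
    f <- factor(out[[nm]])
    if (nlevels(f) < 2)
      stop_arg("factor '%s' has fewer than 2 observed levels", nm)
    contrasts(f) <- stats::contr.sum(nlevels(f))
    out[[nm]] <- f
  }
  out
}

#' Factorial ANOVA with effect coding
#'
#' Least-squares fit of all main effects and interactions up to
#' `interaction_order`, with sum-to-zero (effect) coding and partial
#' (Type-III-style) sums of squares. On balanced data this reproduces the
#' classical order-invariant sequential decomposition exactly; on unbalanced
#' data it is the convention that reduces to the balanced answer. F is the
#' effect mean square over the residual mean square of the full model.
#'
#' @param response numeric response, one value per subject.
#' @param subjects subject-factor data frame (same row order as `response`).
#' @param factor_names character vector of factor columns to include.
#' @param interaction_order highest interaction order (1 = main effects only;
#'   default 2 = all two-way interactions).
#' @return data frame of class `anova_table`: one row per effect
#'   (`effect`, `ss`, `df_num`, `df_den`, `F`, `p`) plus a `Residuals` row.
#' @export
factorial_anova <- function(response, subjects,
                            factor_names = c("piano", "age_group",
                                             "intelligence", "gender"),
                            interaction_order = 2L) {
  if (length(response) != nrow(subjects))
    stop_arg("response length does not match the subject table")
  if (interaction_order < 1 || interaction_order > length(factor_names))
    stop_arg("interaction_order must be in [1, %d]", length(factor_names))
  dat <- as_effect_factors(subjects, factor_names)
  rhs <- sprintf("(%s)^%d", paste(factor_names, collapse = " + "),
                 interaction_order)
  mm_terms <- stats::terms(stats::as.formula(paste("~", rhs)), data = dat)
  X <- stats::model.matrix(mm_terms, dat)
  asg <- attr(X, "assign")
  labels <- attr(mm_terms, "term.labels")
  n <- nrow(X)

  full <- stats::lm.fit(X, response)
  if (full$rank < ncol(X)) {
    aliased <- unique(labels[asg[full$qr$pivot[-seq_len(full$rank)]]])
    stop_arg("rank-deficient design; aliased effect(s): %s",
             paste(aliased, collapse = ", "))
  }
  df_den <- n - ncol(X)
  if (df_den < 1)
    stop_arg("no residual degrees of freedom (need >= 2 subjects per cell)")
  rss_full <- sum(full$residuals^2)
  ms_res <- rss_full / df_den

  # partial (Type-III-style) SS: refit without the term's columns; with
  # effect coding and balance the columns are orthogonal, so this reduces
  # to the classical sequential decomposition
  rows <- lapply(seq_along(labels), function(i) {
    Xi <- X[, asg != i, drop = FALSE]
    ss <- sum(stats::lm.fit(Xi, response)$residuals^2) - rss_full
    df_num <- sum(asg == i)
    Fv <- (ss / df_num) / ms_res
    data.frame(effect = labels[i], ss = ss, df_num = df_num,
               df_den = df_den, F = Fv,
               p = stats::pf(Fv, df_num, df_den, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- rbind(do.call(rbind, rows),
               data.frame(effect = "Residuals", ss = rss_full,
                          df_num = df_den, df_den = NA_integer_,
                          F = NA_real_, p = NA_real_))
  attr(out, "ms_residual") <- ms_res
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Simple-effect tests within levels of another factor
#'
#' Tests the effect of `target` separately at each level of `within`, using
#' the contrast of unweighted cell means at that level against the pooled
#' residual mean square of the full factorial model -- so the denominator
#' degrees of freedom equal the full model's residual df. With
#' `separate_variance = TRUE` a per-level Welch test is used instead.
#'
#' @param response numeric response per subject.
#' @param subjects subject-factor data frame.
#' @param target factor whose effect is tested.
#' @param within factor whose levels stratify the test.
#' @param factor_names all factors of the full model.
#' @param interaction_order interaction order of the full model.
#' @param separate_variance use per-level Welch tests instead of the pooled
#'   residual MS.
#' @return data frame: one row per level of `within` with the mean
#'   difference (second minus first `target` level), `F`, dfs and `p`.
#' @export
simple_effects <- function(response, subjects, target, within,
                           factor_names = c("piano", "age_group",
                                            "intelligence", "gender"),
                           interaction_order = 2L,
                           separate_variance = FALSE) {
  if (identical(target, within))
    stop_arg("target and within must be different factors")
  if (!all(c(target, within) %in% factor_names))
    stop_arg("target and within must be among the model factors")
  dat <- as_effect_factors(subjects, factor_names)
  dat$.y <- response
  w_levels <- levels(dat[[within]])
  t_levels <- levels(dat[[target]])

  if (separate_variance) {
    rows <- lapply(w_levels, function(wl) {
      sub <- dat[dat[[within]] == wl, ]
      tt <- stats::t.test(sub$.y[sub[[target]] == t_levels[2]],
                          sub$.y[sub[[target]] == t_levels[1]])
      data.frame(within_level = wl, estimate = unname(diff(rev(tt$estimate))),
                 F = unname(tt$statistic)^2, df_num = 1,
                 df_den = unname(tt$parameter), p = tt$p.value,
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }

  full <- factorial_anova(response, subjects, factor_names,
                          interaction_order)
  ms_res <- attr(full, "ms_residual")
  df_den <- full$df_num[full$effect == "Residuals"]

  cell_cols <- factor_names
  cells <- stats::aggregate(dat$.y, by = lapply(dat[cell_cols], identity),
                            FUN = mean)
  names(cells) <- c(cell_cols, "mean")
  counts <- stats::aggregate(dat$.y, by = lapply(dat[cell_cols], identity),
                             FUN = length)
  cells$n <- counts$x

  rows <- lapply(w_levels, function(wl) {
    at <- cells[cells[[within]] == wl, ]
    hi <- at[at[[target]] == t_levels[2], ]
    lo <- at[at[[target]] == t_levels[1], ]
    k <- nrow(hi)
    est <- mean(hi$mean) - mean(lo$mean)
    var_c <- ms_res * (sum(1 / hi$n) + sum(1 / lo$n)) / k^2
    Fv <- est^2 / var_c
    data.frame(within_level = wl, estimate = est, F = Fv, df_num = 1,
               df_den = df_den, p = stats::pf(Fv, 1, df_den,
                                              lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# scalar tests

test_result <- function(type, statistic, df = NA_real_, p, tail = "two",
                        estimate = NA_real_, n = NA_integer_) {
  structure(list(type = type, statistic = unname(statistic),
                 df = unname(df), p = unname(p), tail = tail,
                 estimate = unname(estimate), n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (%s-tailed)\n",
              x$type, x$statistic,
              if (is.na(x$df)) "-" else format(x$df), x$p, x$tail))
  invisible(x)
}

#' One-sample t-test
#'
#' @param values numeric sample (n >= 2, non-degenerate).
#' @param mu0 null mean.
#' @return a `test_result` (two-tailed).
#' @export
one_sample_t <- function(values, mu0 = 0) {
  if (length(values) < 2) stop_arg("one_sample_t needs n >= 2")
  if (stats::sd(values) == 0)
    stop_arg("one_sample_t is undefined for zero-variance input")
  tt <- stats::t.test(values, mu = mu0)
  test_result("t", tt$statistic, tt$parameter, tt$p.value,
              estimate = mean(values), n = length(values))
}

#' Pearson product-moment correlation
#'
#' Two-tailed p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 df.
#'
#' @param x,y numeric vectors (n >= 3, both non-degenerate).
#' @return a `test_result` with the correlation as `statistic`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_arg("x and y must have equal length")
  if (length(x) < 3) stop_arg("pearson_r needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_arg("pearson_r is undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result("r", ct$estimate, ct$parameter, ct$p.value, n = length(x))
}

#' Compare two independent correlations via Fisher's r-to-z
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`; the p-value is
#' standard normal, two-tailed or one-tailed in the direction of the
#' observed difference.
#'
#' @param r1,r2 the two correlations (|r| < 1).
#' @param n1,n2 their sample sizes (>= 4).
#' @param tail `"two"` or `"one"`.
#' @return a `test_result` with `z` as `statistic`.
#' @export
#' @examples
#' fisher_z_compare(-0.448, 64, -0.167, 64, tail = "one") # z = -1.73
fisher_z_compare <- function(r1, n1, r2, n2, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop_arg("correlations must satisfy |r| < 1")
  if (n1 < 4 || n2 < 4) stop_arg("fisher_z_compare needs n >= 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (tail == "two") 2 * stats::pnorm(-abs(z)) else
    stats::pnorm(-abs(z))
  test_result("z", z, p = p, tail = tail, estimate = r1 - r2)
}

#' Factorial ANOVAs over fitted curve parameters
#'
#' Applies [factorial_anova()] independently to the initial performance I,
#' the learning rate R, and the day-1 improvement implied by the curve,
#' `C * (1 - R^(n_train - 1))`.
#'
#' @param estimates per-subject point estimates (`subject_id`, `I`, `C`,
#'   `R`), e.g. from [summarize_fit()].
#' @param subjects subject-factor data frame.
#' @param factor_names,interaction_order passed to [factorial_anova()].
#' @param n_train number of training trials used for the improvement.
#' @return named list of `anova_table`s: `I`, `R`, `improvement`.
#' @export
curve_param_anovas <- function(estimates, subjects,
                               factor_names = c("piano", "age_group",
                                                "intelligence", "gender"),
                               interaction_order = 2L, n_train = 12L) {
  idx <- match(subjects$subject_id, estimates$subject_id)
  if (anyNA(idx))
    stop_arg("estimates are missing subject(s): %s",
             paste(subjects$subject_id[is.na(idx)], collapse = ", "))
  est <- estimates[idx, ]
  list(
    I = factorial_anova(est$I, subjects, factor_names, interaction_order),
    R = factorial_anova(est$R, subjects, factor_names, interaction_order),
    improvement = factorial_anova(curve_improvement(est$C, est$R, n_train),
                                  subjects, factor_names, interaction_order)
  )
}
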