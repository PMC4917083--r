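# Convergence diagnostics: split-chain potential scale reduction (R-hat) and
# effective sample size, both on rank-normalized draws, following the
# rank-normalization recipe of Vehtari, Gelman, Simpson, Carpenter & Buerkner
# (2021), Bayesian Analysis 16(2).

split_chains <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  if (half < 2L) stop_arg("too few draws to split chains")
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[(n - half + 1L):n, , drop = FALSE])
}

rank_normalize <- function(mat) {
  z <- stats::qnorm((rank(mat, ties.method = "average") - 3 / 8) /
                      (length(mat) + 1 / 4))
  matrix(z, nrow = nrow(mat))
}

rhat_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  means <- colMeans(mat)
  vars <- apply(mat, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  var_plus <- (n - 1) / n * W + B / n
  if (W <= 0) return(NA_real_)
  sqrt(var_plus / W)
}

#' Split-chain potential scale reduction
#'
#' The larger of the classical split-chain R-hat on the raw draws and the
#' rank-normalized version (robust to heavy tails); values near 1 indicate
#' convergence.
#'
#' @param mat matrix of draws, iterations x chains.
#' @return scalar R-hat (NA for degenerate, zero-variance draws).
#' @export
rhat <- function(mat) {
  mat <- as.matrix(mat)
  if (stats::var(as.vector(mat)) == 0) return(NA_real_)
  sp <- split_chains(mat)
  max(rhat_basic(sp), rhat_basic(rank_normalize(sp)))
}

#' Rank-normalized split-chain effective sample size
#'
#' Combined-chain autocorrelation estimate with Geyer's initial monotone
#' positive sequence truncation.
#'
#' @param mat matrix of draws, iterations x chains.
#' @return scalar effective sample size (NA for zero-variance draws).
#' @export
ess <- function(mat) {
  mat <- as.matrix(mat)
  if (stats::var(as.vector(mat)) == 0) return(NA_real_)
  z <- rank_normalize(split_chains(mat))
  n <- nrow(z); m <- ncol(z)
  # autocovariance per chain via FFT (biased, 1/n normalization)
  nfft <- stats::nextn(2L * n)
  acov <- vapply(seq_len(m), function(j) {
    x <- z[, j] - mean(z[, j])
    f <- stats::fft(c(x, rep(0, nfft - n)))
    Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (nfft * n)
  }, numeric(n))
  mean_acov <- rowMeans(acov) * n / (n - 1)
  W <- mean(apply(z, 2, stats::var))
  var_plus <- (n - 1) / n * W + n * stats::var(colMeans(z)) / n
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer pairwise sums: truncate at the first negative pair, enforce
  # monotone decrease
  max_pairs <- (n - 1L) %/% 2L
  tau <- rho[1] # lag 0 (= about 1)
  prev <- Inf
  for (k in seq_len(max_pairs)) {
    pair <- rho[2 * k] + rho[2 * k + 1]
    if (is.na(pair) || pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
  }
  tau <- max(tau, 1 / m) # guard against antithetic chains
  min(n * m / tau, n * m * log10(n * m))
}

#' Summarize posterior draws
#'
#' Per-parameter posterior mean, SD, central 95% interval, split-chain
#' rank-normalized R-hat and effective sample size, plus per-subject curve
#' parameter point estimates (posterior means of I, C, R) ready for the
#' downstream factorial analyses.
#'
#' @param fit a `taplearn_fit` from [mcmc_fit()].
#' @return list with `summary` (one row per parameter) and `estimates`
#'   (one row per subject: posterior-mean I, C, R).
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "taplearn_fit"))
  d <- fit$draws
  if (dim(d)[3] < 2L) stop_arg("diagnostics need >= 2 chains")
  if (dim(d)[1] < 100L)
    stop_arg("diagnostics need >= 100 retained draws per chain")
  stats_one <- function(p) {
    mat <- d[, p, ]
    v <- as.vector(mat)
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    c(mean = mean(v), sd = stats::sd(v), q2.5 = q[1], q97.5 = q[2],
      rhat = rhat(mat), ess = ess(mat))
  }
  sm <- t(vapply(seq_along(fit$params), stats_one,
                 c(mean = 0, sd = 0, q2.5 = 0, q97.5 = 0, rhat = 0, ess = 0)))
  summary <- data.frame(parameter = fit$params, sm,
                        check.names = FALSE, stringsAsFactors = FALSE)
  post_mean <- summary$mean
  names(post_mean) <- fit$params
  estimates <- data.frame(
    subject_id = fit$subjects,
    I = unname(post_mean[sprintf("I[%s]", fit$subjects)]),
    C = unname(post_mean[sprintf("C[%s]", fit$subjects)]),
    R = unname(post_mean[sprintf("R[%s]", fit$subjects)]),
    stringsAsFactors = FALSE)
  list(summary = summary, estimates = estimates)
}
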