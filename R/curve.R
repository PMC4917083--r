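#' Power-law learning curve
#'
#' Expected performance on trial `t` of the training session:
#' `Y(t) = I + C * (1 - R^(t-1))`, where `I` is the initial performance at
#' trial one, `C` the change in performance across the session (so `I + C` is
#' the asymptote), and `R` in (0, 1) the learning rate -- smaller values mean
#' the plateau is approached faster.
#'
#' @param I initial performance (sequences/trial).
#' @param C performance change across the session (sequences/trial).
#' @param R learning rate.
#' @param t trial index (integer-valued, >= 1); vectorized.
#' @return expected correct sequences per trial, same length as `t`.
#' @export
#' @examples
#' learning_curve(5, 10, 0.5, 1:3) # 5, 10, 12.5
learning_curve <- function(I, C, R, t) {
  if (any(t < 1) || any(t != round(t)))
    stop_arg("trial index t must be an integer >= 1")
  I + C * (1 - R^(t - 1))
}

#' Training improvement implied by fitted curve parameters
#'
#' Model value at the last training trial minus the value at trial one:
#' `C * (1 - R^(n_train - 1))`.
#'
#' @param C,R curve parameters (vectorized).
#' @param n_train number of training trials.
#' @return improvement in sequences/trial.
#' @export
curve_improvement <- function(C, R, n_train = 12L) {
  if (n_train < 2) stop_arg("n_train must be >= 2")
  C * (1 - R^(n_train - 1))
}
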