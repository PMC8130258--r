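#' Proper scoring rules for binary food-security forecasts
#'
#' Three scores compare predicted food-security posteriors with held-out
#' outcomes; all are means over households, so concatenating a dataset with
#' itself leaves them unchanged.
#'
#' `brier_score()` uses the binary single-term convention
#' \eqn{mean((p - y)^2)} with `y = 1` for the food-insecure state and `p`
#' the predicted probability of food insecurity; 0 is perfect, lower is
#' better.
#'
#' `information_reward()` is \eqn{mean(1 + log2 p^*)} where `p*` is the
#' predicted probability of the state that occurred: positive when
#' forecasts beat a uniform coin, 1 for certainty, negative when worse than
#' random. Equivalently 1 minus the forecast cross-entropy in bits.
#'
#' `bayesian_information_reward()` scores improvement over a stated prior
#' rather than over a coin. With predicted insecure-probability `p`, prior
#' insecure-probability `q`, and per-class predicted/prior probabilities
#' `p_c`, `q_c`, each case contributes the per-class average of
#' `log2(p_c / q_c)` for the class that occurred and
#' `log2((1 - p_c) / (1 - q_c))` for the other class; predicting exactly
#' the prior scores 0.
#'
#' @param p_insecure numeric vector of predicted probabilities that each
#'   household is food insecure.
#' @param truth integer vector of outcomes (1 = food insecure, 0 = secure).
#' @return A single numeric score.
#' @export
brier_score <- function(p_insecure, truth) {
  check_binary_inputs(p_insecure, truth)
  mean((p_insecure - truth)^2)
}

#' @rdname brier_score
#' @param p_true_state predicted probability of the state that actually
#'   occurred, per case, in (0, 1].
#' @export
information_reward <- function(p_true_state) {
  if (!length(p_true_state)) stop("empty input")
  if (any(!is.finite(p_true_state)) || any(p_true_state <= 0) ||
      any(p_true_state > 1))
    stop("probabilities of the true state must lie in (0, 1]")
  mean(1 + log2(p_true_state))
}

#' @rdname brier_score
#' @param prior_p_insecure the prior probability of food insecurity the
#'   forecasts are judged against (e.g. the training-set frequency), in
#'   (0, 1).
#' @export
bayesian_information_reward <- function(p_insecure, truth, prior_p_insecure) {
  check_binary_inputs(p_insecure, truth)
  if (!is.finite(prior_p_insecure) || prior_p_insecure <= 0 ||
      prior_p_insecure >= 1)
    stop("prior must lie strictly inside (0, 1)")
  if (any(p_insecure <= 0) || any(p_insecure >= 1))
    stop("degenerate predicted probability (exactly 0 or 1)")
  q1 <- prior_p_insecure; q0 <- 1 - prior_p_insecure
  # per-class average of the occurred-class term log2(p_c/q_c) and the
  # non-occurred-class term log2((1-p_c)/(1-q_c)); for two classes the two
  # terms coincide at log2(p_obs / q_obs)
  term_occ <- ifelse(truth == 1L, log2(p_insecure / q1),
                     log2((1 - p_insecure) / q0))
  term_non <- ifelse(truth == 1L, log2((1 - (1 - p_insecure)) / (1 - q0)),
                     log2((1 - p_insecure) / (1 - q1)))
  mean((term_occ + term_non) / 2)
}

check_binary_inputs <- function(p, truth) {
  if (!length(p)) stop("empty input")
  if (length(p) != length(truth)) stop("lengths differ")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]")
  if (!all(truth %in% c(0L, 1L))) stop("truth must be binary 0/1")
  invisible(TRUE)
}
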