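# BIC comparison of fixed-boundary (evidence-only) versus time-varying
# (evidence + time) wait/go models.

#' Bayesian Information Criterion
#'
#' `BIC = k log(n) - 2 log L`.
#'
#' @param log_likelihood Maximised log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations (>= 1).
#' @return The BIC value (smaller is better).
#' @examples
#' bic(-100, 3, 1000)  # 3 * log(1000) + 200
#' @export
bic <- function(log_likelihood, k, n) {
  if (n < 1) abort("`n` must be at least 1.")
  if (k < 0) abort("`k` must be nonnegative.")
  k * log(n) - 2 * log_likelihood
}

#' Compare fixed and time-varying boundary models
#'
#' Fits the wait/go logistic regression with (`go ~ T + X`, the time-varying
#' boundary) and without (`go ~ X`, the fixed boundary) the time predictor,
#' and compares them by BIC. The posterior probability of the time-varying
#' model under equal priors is computed stably from the BIC difference. A
#' difference smaller than `margin` in magnitude is reported as ambiguous.
#'
#' @param table A [build_wait_go_table()] result containing both actions.
#' @param margin Ambiguity margin on `|delta_bic|` (default 2).
#' @param n_method Observation count used in the BIC: `"rows"` counts every
#'   wait/go opportunity (default), `"trials"` counts decisions (go rows),
#'   for sensitivity analysis.
#' @return One-row tibble of class `waitgo_comparison`: `bic_fixed`,
#'   `bic_varying`, `delta_bic` (fixed minus varying; positive favours the
#'   time-varying model), `post_prob_varying`, `winner`.
#' @export
compare_boundary_models <- function(table, margin = 2,
                                    n_method = c("rows", "trials")) {
  n_method <- arg_match(n_method)
  fit_var <- fit_waitgo_logistic(table, include_time = TRUE)
  fit_fix <- fit_waitgo_logistic(table, include_time = FALSE)
  n <- if (n_method == "rows") nrow(table) else sum(table$action == "go")
  bic_var <- bic(fit_var$log_likelihood, length(fit_var$coef), n)
  bic_fix <- bic(fit_fix$log_likelihood, length(fit_fix$coef), n)
  delta <- bic_fix - bic_var
  post_var <- plogis(delta / 2)  # exp(-bv/2) / (exp(-bv/2) + exp(-bf/2))
  winner <- if (abs(delta) < margin) {
    "ambiguous"
  } else if (delta > 0) {
    "varying"
  } else {
    "fixed"
  }
  out <- tibble(
    bic_fixed = bic_fix, bic_varying = bic_var, delta_bic = delta,
    post_prob_varying = post_var, winner = winner
  )
  class(out) <- c("waitgo_comparison", class(out))
  out
}
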