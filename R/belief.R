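# Belief updating on the (t, x) evidence lattice.
#
# After t cues with running sum x there were n+ = (t+x)/2 up cues and
# n- = (t-x)/2 down cues. Likelihoods are scaled by 2^t (each Bernoulli term
# multiplied by 2) so that products stay well inside double range for the
# horizons used here; posteriors are ratios and unaffected by the scaling.

check_state <- function(t, x) {
  if (t < 0 || t != round(t)) abort("`t` must be a nonnegative integer.")
  if (x != round(x)) abort("`x` must be an integer.")
  if (abs(x) > t) abort("invalid state: |x| must not exceed t.")
  if ((t + x) %% 2 != 0) {
    abort("invalid state: t + x must be even (parity of a +/-1 walk).")
  }
  invisible(TRUE)
}

#' Posterior beliefs at a point of the evidence lattice
#'
#' Given `t` observed cues summing to `x`, returns the posterior probability
#' of each world state, the posterior over the task's drift levels, and the
#' predictive probability that the next cue is +1. In single-difficulty tasks
#' the world posterior depends on `x` alone; in mixed-difficulty tasks elapsed
#' time is itself informative, because uninformative cue streams favour the
#' low-drift level.
#'
#' @param t Number of cues observed (nonnegative integer).
#' @param x Accumulated evidence (integer, `|x| <= t`, `t + x` even).
#' @param task A [task_config()] object.
#'
#' @return A list of class `waitgo_belief` with elements `p_world` (named
#'   probabilities for `up`/`down`), `p_difficulty` (named by drift),
#'   `p_step_up`, and `p_correct` (the larger world posterior).
#' @examples
#' belief_at(4, 4, task_config(0.2, d_correct = 70, d_incorrect = 70))
#' @export
belief_at <- function(t, x, task) {
  stopifnot(is_waitgo_task(task))
  check_state(t, x)
  np <- (t + x) / 2
  nm <- (t - x) / 2
  a <- 1 + 2 * task$drifts   # 2u for world aligned with the cue
  b <- 1 - 2 * task$drifts
  lik_up <- a^np * b^nm      # per drift level, world = up
  lik_dn <- b^np * a^nm
  w <- task$weights
  pu <- task$prior_up
  joint <- c(up = pu * w * lik_up, down = (1 - pu) * w * lik_dn)
  post_up <- sum(pu * w * lik_up) / sum(pu * w * lik_up + (1 - pu) * w * lik_dn)
  p_diff <- (w * (pu * lik_up + (1 - pu) * lik_dn))
  p_diff <- p_diff / sum(p_diff)
  u_up <- 0.5 + task$drifts
  u_dn <- 0.5 - task$drifts
  p_step <- sum(pu * w * lik_up * u_up + (1 - pu) * w * lik_dn * u_dn) /
    sum(pu * w * lik_up + (1 - pu) * w * lik_dn)
  structure(
    list(
      p_world = c(up = post_up, down = 1 - post_up),
      p_difficulty = setNames(p_diff, as.character(task$drifts)),
      p_step_up = p_step,
      p_correct = max(post_up, 1 - post_up)
    ),
    class = "waitgo_belief"
  )
}

#' @export
print.waitgo_belief <- function(x, ...) {
  cat("<waitgo_belief>\n")
  cat("  P(up)      =", format(x$p_world[["up"]]), "\n")
  cat("  P(drift)   =", paste(names(x$p_difficulty), "->",
                              format(x$p_difficulty), collapse = "; "), "\n")
  cat("  P(next +1) =", format(x$p_step_up), "\n")
  invisible(x)
}

# Lattice-wide belief grids used by the dynamic-programming solver.
#
# Matrices are (t_max + 1) x (2 t_max + 1); row t + 1 holds time t, column
# x + t_max + 1 holds evidence x. Invalid states (|x| > t or odd t + x) are NA.
# Returns p_correct (larger world posterior) and p_step_up per state.
belief_grid <- function(task, t_max) {
  width <- 2L * t_max + 1L
  xs <- (-t_max):t_max
  tmat <- matrix(0:t_max, nrow = t_max + 1L, ncol = width)
  xmat <- matrix(xs, nrow = t_max + 1L, ncol = width, byrow = TRUE)
  valid <- abs(xmat) <= tmat & (tmat + xmat) %% 2L == 0L
  np <- (tmat + xmat) / 2
  nm <- (tmat - xmat) / 2
  num_up <- num_dn <- num_step <- matrix(0, t_max + 1L, width)
  pu <- task$prior_up
  for (j in seq_along(task$drifts)) {
    a <- 1 + 2 * task$drifts[j]
    b <- 1 - 2 * task$drifts[j]
    w <- task$weights[j]
    lu <- a^np * b^nm
    ld <- b^np * a^nm
    num_up <- num_up + pu * w * lu
    num_dn <- num_dn + (1 - pu) * w * ld
    num_step <- num_step +
      pu * w * lu * (0.5 + task$drifts[j]) +
      (1 - pu) * w * ld * (0.5 - task$drifts[j])
  }
  den <- num_up + num_dn
  p_up <- num_up / den
  p_correct <- pmax(p_up, 1 - p_up)
  p_step_up <- num_step / den
  p_correct[!valid] <- NA_real_
  p_step_up[!valid] <- NA_real_
  list(
    t_max = t_max, xs = xs, valid = valid,
    p_correct = p_correct, p_step_up = p_step_up
  )
}
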