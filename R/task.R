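#' Define a Bernoulli-cue decision task
#'
#' A task is a sequence of independent two-alternative trials. On each trial
#' the world is "up" (with probability `prior_up`) or "down", and cues
#' \eqn{\delta X \in \{+1, -1\}} arrive one per interstimulus interval (ISI),
#' each pointing toward the true state with probability \eqn{u = 1/2 + \epsilon}
#' (drift \eqn{\epsilon \in [0, 1/2]}; larger drift means an easier trial).
#' A correct choice earns `reward` and is followed by a delay of `d_correct`
#' ISI units; an incorrect choice earns nothing and is followed by
#' `d_incorrect` units. Mixed-difficulty tasks draw the drift of each trial
#' from `drifts` with probabilities `weights`, without telling the decision
#' maker which drift applies.
#'
#' All times are expressed in ISI units so that the same task object serves
#' experiments run at different presentation rates.
#'
#' @param drifts Numeric vector of drift magnitudes in `[0, 0.5]`. A single
#'   value gives a single-difficulty task.
#' @param weights Mixture probabilities for `drifts`; must sum to 1. Defaults
#'   to equal weights.
#' @param d_correct,d_incorrect Intertrial delays (ISI units) after correct
#'   and incorrect choices. Both nonnegative, not both zero.
#' @param reward Reward per correct decision (arbitrary units).
#' @param prior_up Prior probability that the world is "up".
#'
#' @return An object of class `waitgo_task`.
#' @examples
#' task_config(0.2, d_correct = 70, d_incorrect = 70)
#' task_config(c(0.22, 0), d_correct = 50 / 3, d_incorrect = 50)
#' @export
task_config <- function(drifts, weights = NULL, d_correct, d_incorrect,
                        reward = 1, prior_up = 0.5) {
  if (!is.numeric(drifts) || length(drifts) < 1L) {
    abort("`drifts` must be a nonempty numeric vector.")
  }
  if (any(drifts < 0 | drifts > 0.5)) {
    abort("all drifts must lie in [0, 0.5].")
  }
  if (is.null(weights)) weights <- rep(1 / length(drifts), length(drifts))
  if (length(weights) != length(drifts) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must be nonnegative, match `drifts` and sum to 1.")
  }
  if (d_correct < 0 || d_incorrect < 0) {
    abort("intertrial delays must be nonnegative.")
  }
  if (d_correct == 0 && d_incorrect == 0 && reward > 0) {
    abort("both intertrial delays are zero: reward rate is unbounded.")
  }
  if (reward < 0) abort("`reward` must be nonnegative.")
  if (prior_up < 0 || prior_up > 1) abort("`prior_up` must be in [0, 1].")
  structure(
    list(
      drifts = as.double(drifts),
      weights = as.double(weights),
      d_correct = as.double(d_correct),
      d_incorrect = as.double(d_incorrect),
      reward = as.double(reward),
      prior_up = as.double(prior_up)
    ),
    class = "waitgo_task"
  )
}

#' @export
print.waitgo_task <- function(x, ...) {
  kind <- if (length(x$drifts) == 1L) "single-difficulty" else "mixed-difficulty"
  cat("<waitgo_task> ", kind, "\n", sep = "")
  cat("  drifts:  ", paste0(format(x$drifts), " (w=", format(x$weights), ")",
                            collapse = ", "), "\n", sep = "")
  cat("  delays:  D_C = ", format(x$d_correct), ", D_I = ",
      format(x$d_incorrect), " ISI units\n", sep = "")
  cat("  reward:  ", format(x$reward), " per correct; prior_up = ",
      format(x$prior_up), "\n", sep = "")
  invisible(x)
}

is_waitgo_task <- function(x) inherits(x, "waitgo_task")

# Draw a trial difficulty from the task mixture.
draw_difficulty <- function(task) {
  if (length(task$drifts) == 1L) return(task$drifts)
  sample(task$drifts, 1L, prob = task$weights)
}
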