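# Average-reward dynamic programming for wait/go policies.
#
# States are lattice points (t, x). Action `wait` costs one ISI unit and moves
# to (t + 1, x +/- 1) with the predictive cue probability; action `go` earns
# reward R with probability P_c (the larger world posterior), costs the
# realised intertrial delay (D_C on a correct choice, D_I otherwise) and
# returns to (0, 0). With gain rho (reward per ISI unit), the differential
# value h satisfies
#
#   h(t, x) = max( -rho + E[h(t + 1, x +/- 1)],
#                  R P_c - rho (P_c D_C + (1 - P_c) D_I) + h(0, 0) )
#
# with h(0, 0) = 0 and forced go at the truncation horizon t_max. For fixed
# rho the wait transitions are acyclic in t, so h is computed exactly by one
# backward sweep; the optimal gain is the root of rho -> h_rho(0, 0), which is
# strictly decreasing because every action consumes time.

new_waitgo_policy <- function(go, t_max, task, gain, source) {
  structure(
    list(go = go, t_max = as.integer(t_max), task = task,
         gain = gain, source = source),
    class = "waitgo_policy"
  )
}

# One backward sweep at a fixed candidate gain. Returns h(0,0) and, if
# `actions`, the full go map (TRUE = go) with ties broken toward go.
backward_sweep <- function(grids, task, rho, actions = FALSE, tie_tol = 1e-9) {
  t_max <- grids$t_max
  width <- 2L * t_max + 1L
  R <- task$reward
  dc <- task$d_correct
  di <- task$d_incorrect
  go_val <- R * grids$p_correct -
    rho * (grids$p_correct * dc + (1 - grids$p_correct) * di)
  go <- if (actions) matrix(NA, t_max + 1L, width) else NULL
  h_next <- go_val[t_max + 1L, ]
  if (actions) go[t_max + 1L, grids$valid[t_max + 1L, ]] <- TRUE
  for (t in (t_max - 1L):0L) {
    row <- t + 1L
    idx <- which(grids$valid[row, ])
    p <- grids$p_step_up[row, idx]
    wait_val <- -rho + p * h_next[idx + 1L] + (1 - p) * h_next[idx - 1L]
    gv <- go_val[row, idx]
    h_row <- rep(NA_real_, width)
    h_row[idx] <- pmax(gv, wait_val)
    if (actions) go[row, idx] <- gv >= wait_val - tie_tol
    h_next <- h_row
    if (t == 0L) return(list(h00 = h_row[t_max + 1L], go = go))
  }
}

#' Solve for the reward-rate-optimal wait/go policy
#'
#' Computes the policy that maximises the long-run reward rate (reward per ISI
#' unit) for a [task_config()], by Bayesian belief updating over world state
#' and drift level combined with average-reward dynamic programming on the
#' `(t, x)` evidence lattice. For single-difficulty tasks the optimal boundary
#' is constant in time; mixing an easy drift with a very hard one makes the
#' optimal boundary collapse toward zero, while mixing two moderate drifts can
#' make it rise.
#'
#' @param task A [task_config()].
#' @param t_max Truncation horizon in ISI units; all states at `t_max` are
#'   forced to go. The returned policy is invariant to enlarging `t_max`
#'   whenever the wait region ends before the horizon.
#' @param tol Convergence tolerance on the gain.
#' @param tie_tol Value difference below which wait/go ties are resolved
#'   toward go (gives the lowest boundary consistent with optimality).
#'
#' @return A `waitgo_policy`: the wait/go action map plus the achieved gain
#'   `rho` (see `glance()`), tidyable to a `(t, x, action)` tibble with
#'   [tidy()].
#' @examples
#' task <- task_config(0.2, d_correct = 70, d_incorrect = 70)
#' pol <- solve_optimal_policy(task, t_max = 60)
#' glance(pol)
#' @seealso [extract_boundary()], [evaluate_reward_rate()]
#' @export
solve_optimal_policy <- function(task, t_max = 100, tol = 1e-10,
                                 tie_tol = 1e-9) {
  stopifnot(is_waitgo_task(task))
  if (t_max < 1) abort("`t_max` must be at least 1.")
  if (tol <= 0) abort("`tol` must be positive.")
  grids <- belief_grid(task, as.integer(t_max))
  f <- function(rho) backward_sweep(grids, task, rho)$h00
  min_delay <- min(task$d_correct, task$d_incorrect)
  hi <- max(1, task$reward) * 4 / max(min_delay, 0.25)
  root <- tryCatch(
    uniroot(f, interval = c(0, hi), extendInt = "downX",
            tol = tol, maxiter = 10000L),
    error = function(e) {
      abort(paste0("gain iteration failed to converge: ", conditionMessage(e)))
    }
  )
  rho <- root$root
  sweep <- backward_sweep(grids, task, rho, actions = TRUE, tie_tol = tie_tol)
  new_waitgo_policy(sweep$go, t_max, task, gain = rho, source = "optimal")
}

#' @export
print.waitgo_policy <- function(x, ...) {
  n_wait <- sum(!x$go, na.rm = TRUE)
  cat("<waitgo_policy> (", x$source, ")\n", sep = "")
  cat("  t_max =", x$t_max, "|", n_wait, "wait states")
  if (!is.na(x$gain)) cat(" | gain =", format(x$gain, digits = 6))
  cat("\n")
  invisible(x)
}

#' @describeIn solve_optimal_policy long `(t, x, action)` tibble of the
#'   action map over all parity-valid states.
#' @param x,object A `waitgo_policy`.
#' @param ... Unused.
#' @export
tidy.waitgo_policy <- function(x, ...) {
  t_max <- x$t_max
  xs <- (-t_max):t_max
  idx <- which(!is.na(x$go), arr.ind = TRUE)
  acts <- ifelse(x$go[idx], "go", "wait")
  tibble(t = idx[, 1] - 1L, x = xs[idx[, 2]], action = acts) |>
    arrange(.data$t, .data$x)
}

#' @describeIn solve_optimal_policy one-row summary (gain, horizon, state
#'   counts).
#' @export
glance.waitgo_policy <- function(x, ...) {
  tibble(
    gain = x$gain,
    t_max = x$t_max,
    n_states = sum(!is.na(x$go)),
    n_wait = sum(!x$go, na.rm = TRUE),
    source = x$source
  )
}

#' Extract the decision boundary implied by a policy
#'
#' For each time `t`, the boundary height `theta(t)` is the smallest
#' nonnegative evidence level at which the policy's action is go (the policy's
#' go-frontier in the upper half-plane; the lower bound is `-theta(t)` by
#' symmetry). When the innermost parity-valid state at `t` (`x = 0` at even
#' times, `|x| = 1` at odd times, where `x = 0` does not exist) is itself a
#' go state, `theta(t) = 0`: the policy guesses immediately, and no lower
#' boundary is distinguishable on the lattice. At times where no parity-valid
#' state at or above zero is a go state (the frontier lies above the
#' reachable cone `|x| <= t`), `theta` is `NA`. Because the lattice only
#' holds states with `t + x` even, a constant underlying threshold appears as
#' heights alternating between consecutive integers across odd and even `t`.
#'
#' @param policy A `waitgo_policy`.
#' @return A tibble of class `waitgo_boundary` with columns `t` and `theta`.
#' @examples
#' task <- task_config(0.2, d_correct = 70, d_incorrect = 70)
#' extract_boundary(solve_optimal_policy(task, t_max = 60))
#' @export
extract_boundary <- function(policy) {
  stopifnot(inherits(policy, "waitgo_policy"))
  t_max <- policy$t_max
  xs <- (-t_max):t_max
  theta <- vapply(0:t_max, function(t) {
    row <- policy$go[t + 1L, ]
    ok <- which(!is.na(row) & row & xs >= 0)
    if (length(ok) == 0L) return(NA_real_)
    inner <- xs[min(ok)]
    if (inner <= t %% 2L) 0 else as.double(inner)
  }, numeric(1))
  out <- tibble(t = 0:t_max, theta = theta)
  class(out) <- c("waitgo_boundary", class(out))
  attr(out, "gain") <- policy$gain
  out
}
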