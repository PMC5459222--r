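# Exact reward-rate evaluation of boundary policies, and the reward-rate
# landscape over linear boundaries.

#' Define a linear decision boundary
#'
#' A symmetric boundary `theta(t) = max(0, intercept + tan(slope_deg) * t)`
#' in evidence units, with the slope expressed in degrees:
#' `slope_deg = atan(gradient)` for a gradient in evidence units per ISI unit.
#' Negative slopes collapse toward zero (eventually forcing a guess at
#' `x = 0`); the zero boundary guesses immediately.
#'
#' @param intercept Boundary height at `t = 0`, in evidence units.
#' @param slope_deg Slope in degrees, strictly inside (-90, 90).
#' @return An object of class `waitgo_linear_boundary`.
#' @examples
#' linear_boundary(3, 0)     # constant threshold at 3
#' linear_boundary(3, -45)   # collapses to 0 at t = 3
#' @export
linear_boundary <- function(intercept, slope_deg = 0) {
  if (!is.numeric(intercept) || length(intercept) != 1L) {
    abort("`intercept` must be a single number.")
  }
  if (slope_deg <= -90 || slope_deg >= 90) {
    abort("`slope_deg` must lie strictly inside (-90, 90).")
  }
  structure(
    list(intercept = as.double(intercept), slope_deg = as.double(slope_deg),
         gradient = tan(slope_deg * pi / 180)),
    class = "waitgo_linear_boundary"
  )
}

#' @export
print.waitgo_linear_boundary <- function(x, ...) {
  cat("<waitgo_linear_boundary> theta(t) = max(0, ",
      format(x$intercept), " + ", format(x$gradient, digits = 4),
      " t)  [slope ", format(x$slope_deg), " deg]\n", sep = "")
  invisible(x)
}

#' Boundary height as a function of time
#'
#' Evaluates `theta(t)` for a boundary specification: a
#' [linear_boundary()], a `waitgo_boundary` extracted from a policy (values
#' beyond its horizon are 0, times whose frontier is unreachable are `Inf`),
#' or a single number (constant threshold).
#'
#' @param boundary Boundary specification.
#' @param t Integer vector of times (ISI units).
#' @return Numeric vector of boundary heights.
#' @export
boundary_height <- function(boundary, t) {
  if (inherits(boundary, "waitgo_linear_boundary")) {
    return(pmax(0, boundary$intercept + boundary$gradient * t))
  }
  if (inherits(boundary, "waitgo_boundary")) {
    theta <- boundary$theta
    t_max <- max(boundary$t)
    out <- ifelse(t > t_max, 0, theta[pmin(t, t_max) + 1L])
    out[is.na(out)] <- Inf
    return(out)
  }
  if (is.numeric(boundary) && length(boundary) == 1L) {
    return(rep(as.double(boundary), length(t)))
  }
  abort("unsupported boundary specification.")
}

#' Convert a linear boundary to a wait/go policy grid
#'
#' Actions are go wherever `|x| >= theta(t)` (boundary states are go, so a
#' zero or negative height forces an immediate guess) and wait strictly
#' inside the boundary; all states at the horizon `t_max` are forced to go.
#'
#' @param boundary A [linear_boundary()] (or any [boundary_height()] input).
#' @param t_max Truncation horizon (ISI units).
#' @param task Optionally attach a [task_config()] to the policy.
#' @return A `waitgo_policy` (gain `NA` until evaluated).
#' @examples
#' policy_from_linear_boundary(linear_boundary(3, -45), t_max = 20)
#' @export
policy_from_linear_boundary <- function(boundary, t_max = 100, task = NULL) {
  if (t_max < 1) abort("`t_max` must be at least 1.")
  t_max <- as.integer(t_max)
  xs <- (-t_max):t_max
  theta <- boundary_height(boundary, 0:t_max)
  tmat <- matrix(0:t_max, t_max + 1L, 2L * t_max + 1L)
  xmat <- matrix(xs, t_max + 1L, 2L * t_max + 1L, byrow = TRUE)
  valid <- abs(xmat) <= tmat & (tmat + xmat) %% 2L == 0L
  go <- abs(xmat) >= theta[tmat + 1L]
  go[t_max + 1L, ] <- TRUE
  go[!valid] <- NA
  new_waitgo_policy(go, t_max, task, gain = NA_real_, source = "linear")
}

# Per-difficulty absorption statistics of a boundary policy: exact forward
# propagation of the +/-1 walk occupancy in the "up" world (symmetric
# policies make the "down" world its mirror image). Mass in a go state is
# absorbed; the response is the sign of x (a fair coin at x = 0).
trial_statistics <- function(policy, task = NULL) {
  stopifnot(inherits(policy, "waitgo_policy"))
  task <- task %||% policy$task
  stopifnot(is_waitgo_task(task))
  t_max <- policy$t_max
  width <- 2L * t_max + 1L
  centre <- t_max + 1L
  xs <- (-t_max):t_max
  res <- purrr::map(seq_along(task$drifts), function(j) {
    u <- 0.5 + task$drifts[j]
    occ <- numeric(width)
    occ[centre] <- 1
    p_correct <- 0
    e_t <- 0
    for (t in 0:t_max) {
      row <- policy$go[t + 1L, ]
      go_idx <- which(!is.na(row) & row & occ > 0)
      if (length(go_idx)) {
        m <- occ[go_idx]
        p_correct <- p_correct + sum(m * (xs[go_idx] > 0)) +
          0.5 * sum(m * (xs[go_idx] == 0))
        e_t <- e_t + t * sum(m)
        occ[go_idx] <- 0
      }
      if (t == t_max) break
      nxt <- numeric(width)
      live <- which(occ > 0)
      if (length(live) == 0L) break
      nxt[live + 1L] <- nxt[live + 1L] + occ[live] * u
      nxt[live - 1L] <- nxt[live - 1L] + occ[live] * (1 - u)
      occ <- nxt
    }
    c(p_correct = p_correct, e_samples = e_t)
  })
  tibble(
    drift = task$drifts,
    weight = task$weights,
    p_correct = vapply(res, `[[`, numeric(1), "p_correct"),
    e_samples = vapply(res, `[[`, numeric(1), "e_samples")
  )
}

#' Exact reward rate of a boundary policy
#'
#' Computes the long-run reward per ISI unit of a wait/go policy under a task
#' by exact forward propagation of the evidence random walk: per drift level
#' the probability of a correct choice `P_c` and the expected number of cues
#' at decision `E[T]` are obtained from the absorption distribution, then
#' combined over the difficulty mixture as a renewal-reward ratio
#' \deqn{\rho = \frac{R \, \bar P_c}{\bar E[T] + \bar{(P_c D_C + (1 - P_c)
#' D_I)}}.}
#'
#' The policy must be symmetric about `x = 0` (all policies produced by this
#' package are); only the "up" world is propagated.
#'
#' @param policy A `waitgo_policy` (its wait region is finite because the
#'   horizon forces go).
#' @param task A [task_config()]; defaults to the task attached to the policy.
#' @return The reward rate (a single double).
#' @examples
#' task <- task_config(0.2, d_correct = 10, d_incorrect = 10)
#' evaluate_reward_rate(policy_from_linear_boundary(linear_boundary(1), 50), task)
#' # closed form: 0.7 / (1 + 10)
#' @export
evaluate_reward_rate <- function(policy, task = NULL) {
  task <- task %||% policy$task
  stopifnot(is_waitgo_task(task))
  st <- trial_statistics(policy, task)
  num <- task$reward * sum(st$weight * st$p_correct)
  den <- sum(st$weight * (st$e_samples +
                            st$p_correct * task$d_correct +
                            (1 - st$p_correct) * task$d_incorrect))
  num / den
}

#' Reward-rate landscape over linear boundaries
#'
#' Evaluates the exact reward rate of every linear boundary on a grid of
#' slopes (degrees) and intercepts (evidence units). Intercepts default to
#' integers because evidence lives on an integer lattice, so fractional
#' constant boundaries are indistinguishable from the next integer up.
#'
#' @param task A [task_config()].
#' @param slopes_deg Grid of slopes in degrees.
#' @param intercepts Grid of intercepts.
#' @param t_max Truncation horizon for each boundary policy.
#' @return A tibble of class `waitgo_landscape` with columns `slope_deg`,
#'   `intercept`, `reward_rate`. The grid maximum is recorded in the
#'   `argmax` attribute (ties broken toward the lowest intercept, then the
#'   slope nearest zero) and reported by `glance()`.
#' @examples
#' task <- task_config(0.22, d_correct = 50 / 3, d_incorrect = 50)
#' ls <- reward_landscape(task, slopes_deg = c(-20, 0, 20), intercepts = 0:5,
#'                        t_max = 60)
#' glance(ls)
#' @export
reward_landscape <- function(task, slopes_deg = seq(-80, 80, by = 2),
                             intercepts = 0:15, t_max = 100) {
  stopifnot(is_waitgo_task(task))
  if (length(slopes_deg) == 0L || length(intercepts) == 0L) {
    abort("slope and intercept grids must be nonempty.")
  }
  grid <- tidyr::expand_grid(slope_deg = slopes_deg, intercept = intercepts)
  grid$reward_rate <- purrr::map2_dbl(
    grid$slope_deg, grid$intercept,
    function(s, a) {
      evaluate_reward_rate(
        policy_from_linear_boundary(linear_boundary(a, s), t_max), task
      )
    }
  )
  best <- grid |>
    filter(.data$reward_rate >= max(.data$reward_rate)) |>
    arrange(.data$intercept, abs(.data$slope_deg), .data$slope_deg) |>
    head(1L)
  out <- grid
  class(out) <- c("waitgo_landscape", class(out))
  attr(out, "argmax") <- as.list(best)
  attr(out, "task") <- task
  attr(out, "t_max") <- t_max
  out
}

#' @describeIn reward_landscape one-row tibble with the argmax cell and the
#'   maximal rate.
#' @param x A `waitgo_landscape`.
#' @param ... Unused.
#' @export
glance.waitgo_landscape <- function(x, ...) {
  am <- attr(x, "argmax")
  tibble(
    slope_deg = am$slope_deg, intercept = am$intercept,
    reward_rate = am$reward_rate,
    n_cells = nrow(x), t_max = attr(x, "t_max")
  )
}
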