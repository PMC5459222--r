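# Synthetic expanded-judgment cohorts: Bernoulli cue streams, fixed-duration
# blocks, and the two agent families used for boundary-recovery studies.

#' Generate a Bernoulli cue sequence
#'
#' Draws `n` i.i.d. cues \eqn{\delta X \in \{+1, -1\}}, +1 with probability
#' `u`.
#'
#' @param u Up-probability in `[0, 1]`.
#' @param n Sequence length.
#' @return Integer vector of +1/-1 values.
#' @examples
#' set.seed(1)
#' mean(generate_cues(0.7, 1e4))  # close to 2 * 0.7 - 1
#' @export
generate_cues <- function(u, n) {
  if (u < 0 || u > 1) abort("`u` must be in [0, 1].")
  if (n < 0) abort("`n` must be nonnegative.")
  if (n == 0) return(integer(0))
  2L * rbinom(n, 1L, u) - 1L
}

#' Specify a simulated decision maker
#'
#' Two agent families generate wait/go behaviour on the cue stream:
#'
#' * `"threshold"`: integrates cues (possibly noisily and with attentional
#'   loss) and responds the first time the internal evidence magnitude
#'   reaches the boundary `theta(t)` — a rise-to-threshold rule.
#' * `"probabilistic"`: after every cue goes with probability
#'   `plogis(beta0 + betaT * t + betaX * |x|)` applied to the internal state —
#'   a stochastic wait/go boundary.
#'
#' Perturbations shared by both kinds: per-cue Gaussian internal noise of
#' standard deviation `sigma_internal` (so the noise SD after `t` cues is
#' `sigma_internal * sqrt(t)`), trial-to-trial drift variability
#' `sigma_drift` (the trial's drift is perturbed by a Gaussian draw, with the
#' resulting up-probability clamped to `[0.02, 0.98]`), attentional loss
#' `p_attend` (each cue registers independently with this probability), and
#' an integer nondecision lag `nd_samples` (the response is recorded
#' `nd_samples` cues after the internal decision, while presented cues keep
#' arriving).
#'
#' @param kind `"threshold"` or `"probabilistic"`.
#' @param boundary For threshold agents: a [linear_boundary()], a
#'   `waitgo_boundary`, or a single number (constant threshold).
#' @param betas For probabilistic agents: numeric `c(beta0, betaT, betaX)`.
#' @param sigma_internal,sigma_drift,p_attend,nd_samples See above.
#' @param cue_cap Hard per-trial cue limit; a trial hitting it is forced to
#'   respond and flagged.
#' @return An object of class `waitgo_agent`.
#' @examples
#' agent_spec("threshold", boundary = linear_boundary(3, 0))
#' agent_spec("probabilistic", betas = c(-4, 0.2, 1))
#' @export
agent_spec <- function(kind = c("threshold", "probabilistic"),
                       boundary = NULL, betas = NULL,
                       sigma_internal = 0, sigma_drift = 0, p_attend = 1,
                       nd_samples = 0, cue_cap = 500) {
  kind <- arg_match(kind)
  if (kind == "threshold") {
    if (is.null(boundary)) abort("threshold agents need a `boundary`.")
    boundary_height(boundary, 0L)  # validates
  } else {
    if (is.null(betas) || length(betas) != 3L || !is.numeric(betas)) {
      abort("probabilistic agents need `betas = c(beta0, betaT, betaX)`.")
    }
  }
  if (p_attend <= 0 || p_attend > 1) abort("`p_attend` must be in (0, 1].")
  if (sigma_internal < 0 || sigma_drift < 0) {
    abort("noise standard deviations must be nonnegative.")
  }
  if (nd_samples < 0 || nd_samples != round(nd_samples)) {
    abort("`nd_samples` must be a nonnegative integer.")
  }
  structure(
    list(kind = kind, boundary = boundary, betas = betas,
         sigma_internal = sigma_internal, sigma_drift = sigma_drift,
         p_attend = p_attend, nd_samples = as.integer(nd_samples),
         cue_cap = as.integer(cue_cap)),
    class = "waitgo_agent"
  )
}

#' @export
print.waitgo_agent <- function(x, ...) {
  cat("<waitgo_agent> ", x$kind, "\n", sep = "")
  if (x$kind == "probabilistic") {
    cat("  betas: ", paste(format(x$betas), collapse = ", "), "\n", sep = "")
  }
  cat("  sigma_internal = ", x$sigma_internal,
      ", sigma_drift = ", x$sigma_drift,
      ", p_attend = ", x$p_attend,
      ", nd = ", x$nd_samples, "\n", sep = "")
  invisible(x)
}

# Core single-trial simulation; returns a plain list (tibble assembly is done
# once per block for speed).
sim_trial_core <- function(agent, task, difficulty, world) {
  eps <- difficulty
  u <- if (world == "up") 0.5 + eps else 0.5 - eps
  if (agent$sigma_drift > 0) {
    u <- u + (if (world == "up") 1 else -1) * rnorm(1L, 0, agent$sigma_drift)
    u <- min(max(u, 0.02), 0.98)  # keep the Bernoulli draw valid
  }

  cues <- integer(0)
  x_int <- numeric(0)
  t_int <- NA_integer_
  flagged <- FALSE

  theta0 <- if (agent$kind == "threshold") {
    boundary_height(agent$boundary, 0L)
  } else {
    Inf
  }
  if (is.finite(theta0) && theta0 <= 0) {
    t_int <- 0L
  } else {
    chunk <- 64L
    last <- 0
    repeat {
      n_new <- min(chunk, agent$cue_cap - length(cues))
      new_cues <- generate_cues(u, n_new)
      reg <- if (agent$p_attend < 1) {
        new_cues * rbinom(n_new, 1L, agent$p_attend)
      } else {
        new_cues
      }
      inc <- reg + if (agent$sigma_internal > 0) {
        rnorm(n_new, 0, agent$sigma_internal)
      } else {
        0
      }
      ts <- length(cues) + seq_len(n_new)
      xs <- last + cumsum(inc)
      cues <- c(cues, new_cues)
      x_int <- c(x_int, xs)
      last <- xs[n_new]
      if (agent$kind == "threshold") {
        hit <- abs(xs) >= boundary_height(agent$boundary, ts)
      } else {
        p_go <- plogis(agent$betas[1] + agent$betas[2] * ts +
                         agent$betas[3] * abs(xs))
        hit <- runif(n_new) < p_go
      }
      if (any(hit)) {
        t_int <- ts[which(hit)[1]]
        break
      }
      if (length(cues) >= agent$cue_cap) {
        t_int <- length(cues)
        flagged <- TRUE
        break
      }
    }
  }

  ev <- if (t_int == 0L) 0 else x_int[t_int]
  response <- if (ev > 0) "up" else if (ev < 0) "down" else {
    if (runif(1L) < 0.5) "up" else "down"
  }
  nd <- agent$nd_samples
  if (nd > 0L) cues <- c(cues[seq_len(t_int)], generate_cues(u, nd))
  list(
    difficulty = difficulty, world = world, response = response,
    correct = response == world, decision_t = t_int + nd,
    cues = cues[seq_len(t_int + nd)], flagged = flagged
  )
}

cues_to_string <- function(cues) {
  if (length(cues) == 0L) return("")
  paste(ifelse(cues > 0L, "+", "-"), collapse = "")
}

cues_to_steps <- function(s) {
  if (is.na(s) || nchar(s) == 0L) return(integer(0))
  ifelse(strsplit(s, "")[[1]] == "+", 1L, -1L)
}

#' Simulate a single decision trial
#'
#' Runs one trial of an [agent_spec()] on a [task_config()] at a given drift
#' and world state. The recorded cue sequence is what the experimenter
#' presented, including cues arriving during the nondecision lag.
#'
#' @param agent An [agent_spec()].
#' @param task A [task_config()].
#' @param difficulty Trial drift; defaults to a draw from the task mixture.
#' @param world `"up"` or `"down"`; defaults to a draw from `prior_up`.
#' @return A one-row tibble with columns `difficulty`, `world`, `response`,
#'   `correct`, `decision_t`, `cues` (a `+`/`-` string), `flagged`.
#' @examples
#' set.seed(1)
#' ag <- agent_spec("threshold", boundary = 3)
#' simulate_trial(ag, task_config(0.2, d_correct = 15, d_incorrect = 50))
#' @export
simulate_trial <- function(agent, task, difficulty = NULL, world = NULL) {
  stopifnot(inherits(agent, "waitgo_agent"), is_waitgo_task(task))
  difficulty <- difficulty %||% draw_difficulty(task)
  world <- world %||%
    (if (runif(1L) < task$prior_up) "up" else "down")
  tr <- sim_trial_core(agent, task, difficulty, world)
  tibble(
    difficulty = tr$difficulty, world = tr$world, response = tr$response,
    correct = tr$correct, decision_t = tr$decision_t,
    cues = cues_to_string(tr$cues), flagged = tr$flagged
  )
}

#' Simulate a fixed-duration block of trials
#'
#' Trials are run back to back; each consumes its decision time (in cues,
#' i.e. ISI units) plus the realised intertrial delay (`d_correct` or
#' `d_incorrect`). A trial whose decision would land after the block expires
#' is discarded, matching a paradigm that only counts completed choices.
#'
#' @inheritParams simulate_trial
#' @param duration Block duration in ISI units (> 0).
#' @param condition Label stored with each trial (e.g. `"easy"`, `"mixed"`).
#' @param block_id Identifier stored with each trial.
#' @return A tibble with one row per completed trial; columns as in
#'   [simulate_trial()] plus `condition`, `block_id`, `trial_id`.
#' @examples
#' set.seed(1)
#' ag <- agent_spec("threshold", boundary = 3)
#' task <- task_config(0.2, d_correct = 15, d_incorrect = 50)
#' nrow(simulate_block(ag, task, duration = 1200, condition = "easy"))
#' @export
simulate_block <- function(agent, task, duration, condition = "easy",
                           block_id = 1L) {
  stopifnot(inherits(agent, "waitgo_agent"), is_waitgo_task(task))
  if (duration < 0) abort("`duration` must be nonnegative.")
  trials <- list()
  time_used <- 0
  i <- 0L
  while (time_used < duration) {
    difficulty <- draw_difficulty(task)
    world <- if (runif(1L) < task$prior_up) "up" else "down"
    tr <- sim_trial_core(agent, task, difficulty, world)
    if (time_used + tr$decision_t > duration) break  # in progress at expiry
    i <- i + 1L
    delay <- if (tr$correct) task$d_correct else task$d_incorrect
    time_used <- time_used + tr$decision_t + delay
    trials[[i]] <- tr
  }
  if (length(trials) == 0L) {
    return(tibble(
      block_id = integer(0), trial_id = integer(0), condition = character(0),
      difficulty = double(0), world = character(0), response = character(0),
      correct = logical(0), decision_t = integer(0), cues = character(0),
      flagged = logical(0)
    ))
  }
  tibble(
    block_id = as.integer(block_id),
    trial_id = seq_along(trials),
    condition = condition,
    difficulty = vapply(trials, `[[`, numeric(1), "difficulty"),
    world = vapply(trials, `[[`, character(1), "world"),
    response = vapply(trials, `[[`, character(1), "response"),
    correct = vapply(trials, `[[`, logical(1), "correct"),
    decision_t = vapply(trials, `[[`, integer(1), "decision_t"),
    cues = vapply(trials, function(x) cues_to_string(x$cues), character(1)),
    flagged = vapply(trials, `[[`, logical(1), "flagged")
  )
}

#' Simulate a cohort of participants
#'
#' Runs every participant through `n_blocks` fixed-duration blocks of each
#' condition. Per-participant seeds are drawn first and recorded in the
#' output, so a cohort is reproducible either wholesale (same outer seed) or
#' participant by participant.
#'
#' @param n_participants Number of simulated participants (>= 1).
#' @param agent_sampler Either a single [agent_spec()] used for everyone, or
#'   a function `function(participant)` returning an agent (used for all
#'   conditions) or a named list of agents, one per condition.
#' @param tasks Named list of [task_config()] objects, one per condition.
#' @param durations Named numeric vector of block durations (ISI units),
#'   names matching `tasks`.
#' @param n_blocks Blocks per condition.
#' @return A tibble of trial records with `participant` and `seed` columns
#'   prepended.
#' @examples
#' set.seed(1)
#' ag <- agent_spec("threshold", boundary = 3)
#' tasks <- list(easy = task_config(0.2, d_correct = 15, d_incorrect = 50))
#' ch <- simulate_cohort(2, ag, tasks, c(easy = 400), n_blocks = 1)
#' @export
simulate_cohort <- function(n_participants, agent_sampler, tasks, durations,
                            n_blocks = 2L) {
  if (n_participants < 1) abort("`n_participants` must be at least 1.")
  if (!is.list(tasks) || is.null(names(tasks)) ||
      !all(names(tasks) %in% names(durations))) {
    abort("`tasks` must be a named list with matching `durations` entries.")
  }
  seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  out <- purrr::map(seq_len(n_participants), function(p) {
    set.seed(seeds[p])
    agents <- if (inherits(agent_sampler, "waitgo_agent")) {
      agent_sampler
    } else {
      agent_sampler(p)
    }
    cond_rows <- purrr::imap(tasks, function(task, cond) {
      ag <- if (inherits(agents, "waitgo_agent")) agents else agents[[cond]]
      purrr::map(seq_len(n_blocks), function(b) {
        simulate_block(ag, task, durations[[cond]], condition = cond,
                       block_id = b)
      }) |> bind_rows()
    })
    bind_rows(cond_rows) |>
      mutate(participant = p, seed = seeds[p], .before = 1L)
  })
  bind_rows(out)
}
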