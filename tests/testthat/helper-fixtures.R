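# Shared fixtures: small tasks and simulation helpers, all built in code.

task_easy <- function(dc = 50 / 3, di = 50) {
  task_config(0.22, d_correct = dc, d_incorrect = di)
}

task_mixed <- function(dc = 50 / 3, di = 50) {
  task_config(c(0.22, 0), d_correct = dc, d_incorrect = di)
}

# n independent trials of one agent on one task, labelled with a condition.
sim_trials <- function(agent, task, n, condition = "easy") {
  out <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    simulate_trial(agent, task)
  }))
  out$condition <- condition
  out$trial_id <- seq_len(n)
  out
}

# Monte-Carlo reward-rate oracle for a linear boundary: simulates the +/-1
# walk directly (independently of simulate_trial) with forced response at
# t_cap, and returns the plug-in rate estimate plus a batch standard error.
mc_rate_oracle <- function(boundary, task, n = 1e5, t_cap = 300,
                           n_batch = 50) {
  theta <- boundary_height(boundary, 0:t_cap)
  per_drift <- function(eps, n_j) {
    u <- 0.5 + eps
    dt <- integer(n_j)
    corr <- logical(n_j)
    if (theta[1] <= 0) {
      corr <- stats::runif(n_j) < 0.5
      return(list(dt = dt, correct = corr))
    }
    x <- integer(n_j)
    alive <- rep(TRUE, n_j)
    for (t in seq_len(t_cap)) {
      idx <- which(alive)
      if (length(idx) == 0L) break
      x[idx] <- x[idx] + (2L * stats::rbinom(length(idx), 1L, u) - 1L)
      th <- if (t == t_cap) 0 else theta[t + 1L]
      hit <- idx[abs(x[idx]) >= th]
      if (length(hit)) {
        dt[hit] <- t
        ev <- x[hit]
        corr[hit] <- ifelse(ev == 0L, stats::runif(length(hit)) < 0.5,
                            ev > 0L)
        alive[hit] <- FALSE
      }
    }
    list(dt = dt, correct = corr)
  }
  ks <- sample(seq_along(task$drifts), n, replace = TRUE,
               prob = task$weights)
  dt <- integer(n)
  corr <- logical(n)
  for (j in seq_along(task$drifts)) {
    sel <- which(ks == j)
    if (length(sel)) {
      r <- per_drift(task$drifts[j], length(sel))
      dt[sel] <- r$dt
      corr[sel] <- r$correct
    }
  }
  rate_of <- function(i) {
    pc <- mean(corr[i])
    task$reward * pc /
      (mean(dt[i]) + pc * task$d_correct + (1 - pc) * task$d_incorrect)
  }
  batches <- split(seq_len(n), rep(seq_len(n_batch), length.out = n))
  batch_rates <- vapply(batches, rate_of, numeric(1))
  list(rate = rate_of(seq_len(n)),
       se = stats::sd(batch_rates) / sqrt(n_batch))
}
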