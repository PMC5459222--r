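# Overflow-safe log(1 + exp(eta)).
log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

# Recovering decision boundaries from trial records: nondecision time,
# the wait/go logistic regression, the line of indifference, circular slope
# differences, bootstrap confidence intervals, and the chance-level
# exclusion test.

#' Estimate the nondecision lag from response-locked cue agreement
#'
#' Cues arriving after the internal decision (during the nondecision period)
#' cannot have influenced the response, so their direction agrees with the
#' response only at the chance level set by the drift. Reversing each trial's
#' cue sequence and aligning on the response, `p_t` is the proportion of
#' trials whose `t`-th cue before the response matches the response
#' direction. The cue that triggered a rise-to-threshold decision always
#' matches, so `p_t` jumps once the lag is passed: the estimated lag `nd` is
#' one less than the first index with `p_t` above `threshold`.
#'
#' Trials shorter than `t` cues do not enter `p_t`'s denominator. Estimate
#' the lag on single-difficulty easy trials (where the jump is sharpest) and
#' apply it to all conditions of the same paradigm.
#'
#' @param trials Trial-record tibble (columns `cues`, `decision_t`,
#'   `response`).
#' @param threshold Agreement level that marks decision-relevant cues.
#' @param max_lag Largest lag considered; if no index exceeds `threshold`,
#'   `nd = max_lag` and the estimate is flagged `saturated`.
#' @param min_trials Minimum number of usable trials (with at least one cue).
#' @return A list of class `waitgo_nd`: `nd`, `p_series` (tibble `t`, `n`,
#'   `p`), `threshold`, `saturated`.
#' @export
estimate_nondecision <- function(trials, threshold = 0.75, max_lag = 10L,
                                 min_trials = 20L) {
  stopifnot(is.data.frame(trials))
  use <- filter(trials, .data$decision_t >= 1L)
  if (nrow(use) < min_trials) {
    abort(paste0("need at least ", min_trials,
                 " trials with >= 1 cue to estimate the nondecision lag."))
  }
  resp_sign <- ifelse(use$response == "up", 1L, -1L)
  steps <- purrr::map(use$cues, cues_to_steps)
  p_series <- purrr::map(seq_len(max_lag), function(t) {
    has <- use$decision_t >= t
    agree <- purrr::map2_lgl(steps[has], which(has), function(s, i) {
      s[length(s) - t + 1L] == resp_sign[i]
    })
    c(t = t, n = sum(has), p = mean(agree))
  })
  ps <- bind_rows(purrr::map(p_series, as_tibble_row_num))
  above <- which(ps$p > threshold & ps$n > 0L)
  saturated <- length(above) == 0L
  nd <- if (saturated) {
    warn("no response-locked index exceeded the threshold; lag saturated at `max_lag`.")
    as.integer(max_lag)
  } else {
    min(above) - 1L
  }
  structure(
    list(nd = nd, p_series = ps, threshold = threshold,
         saturated = saturated),
    class = "waitgo_nd"
  )
}

as_tibble_row_num <- function(x) {
  tibble(t = as.integer(x[["t"]]), n = as.integer(x[["n"]]), p = x[["p"]])
}

#' @export
print.waitgo_nd <- function(x, ...) {
  cat("<waitgo_nd> nd =", x$nd,
      if (x$saturated) "(saturated)" else "", "\n")
  print(x$p_series, n = 5)
  invisible(x)
}

#' Strip the nondecision lag from trial records
#'
#' Removes the last `nd` cues of every trial and moves the decision state
#' back to `decision_t - nd`. With `nd = 0` the records are returned
#' unchanged. Trials with `decision_t <= nd` (nothing left before the lag)
#' are dropped; the count is available as `attr(., "n_dropped")`.
#'
#' @param trials Trial-record tibble.
#' @param nd Nonnegative integer lag (e.g. from [estimate_nondecision()]).
#' @return The trial tibble with shortened `cues` and `decision_t`.
#' @export
strip_nondecision <- function(trials, nd) {
  stopifnot(is.data.frame(trials))
  if (inherits(nd, "waitgo_nd")) nd <- nd$nd
  if (nd < 0 || nd != round(nd)) abort("`nd` must be a nonnegative integer.")
  nd <- as.integer(nd)
  if (nd == 0L) {
    attr(trials, "n_dropped") <- 0L
    return(trials)
  }
  keep <- trials$decision_t > nd
  out <- trials[keep, , drop = FALSE]
  out$decision_t <- out$decision_t - nd
  out$cues <- substr(out$cues, 1L, out$decision_t)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Expand trial records into the wait/go observation table
#'
#' Every cue the decision maker saw is one wait/go opportunity: a trial that
#' decided at `decision_t = n` contributes wait rows at `t = 1, ..., n - 1`
#' (with the running evidence) and a single go row at its final state. An
#' immediate guess contributes the lone row `(0, 0, go)`. Evidence enters as
#' the folded magnitude `X = |x|`, so the two symmetric boundaries map onto
#' one go-frontier in the upper half-plane.
#'
#' Strip the nondecision lag ([strip_nondecision()]) before building the
#' table.
#'
#' @param trials Trial-record tibble.
#' @param conditions Optional character vector: keep only these conditions.
#' @param easy_only_in_mixed If `TRUE` (default), trials of the mixed
#'   condition whose generating drift is the smallest drift present in that
#'   condition are excluded, so mixed-condition fits use like-for-like
#'   (easy) trials. Set `mixed_difficulty = "difficult"` for the converse.
#' @param mixed_difficulty One of `"easy"`, `"difficult"`, `"all"`;
#'   overrides `easy_only_in_mixed` when given explicitly.
#' @return A tibble (`waitgo_table`) with identifier columns plus `t`, `x`
#'   (folded evidence), `action` (`"wait"`/`"go"`).
#' @examples
#' trials <- tibble::tibble(condition = "easy", difficulty = 0.2,
#'   world = "up", response = "up", correct = TRUE,
#'   decision_t = 3L, cues = "+-+")
#' build_wait_go_table(trials)
#' @export
build_wait_go_table <- function(trials, conditions = NULL,
                                easy_only_in_mixed = TRUE,
                                mixed_difficulty = NULL) {
  stopifnot(is.data.frame(trials))
  if (!is.null(conditions)) {
    trials <- filter(trials, .data$condition %in% conditions)
  }
  mixed_difficulty <- mixed_difficulty %||%
    (if (easy_only_in_mixed) "easy" else "all")
  mixed_difficulty <- arg_match0(mixed_difficulty,
                                 c("easy", "difficult", "all"))
  if (mixed_difficulty != "all" && "condition" %in% names(trials) &&
      any(trials$condition == "mixed")) {
    mixed <- trials$condition == "mixed"
    drifts <- sort(unique(trials$difficulty[mixed]))
    if (length(drifts) > 1L) {
      drop_drift <- if (mixed_difficulty == "easy") {
        drifts[-length(drifts)]
      } else {
        drifts[length(drifts)]
      }
      trials <- trials[!(mixed & trials$difficulty %in% drop_drift), ,
                       drop = FALSE]
    }
  }
  if (nrow(trials) == 0L) {
    return(structure(
      tibble(row = integer(0), t = integer(0), x = integer(0),
             action = character(0)),
      class = c("waitgo_table", class(tibble()))
    ))
  }
  id_cols <- intersect(
    c("participant", "condition", "block_id", "trial_id", "difficulty"),
    names(trials)
  )
  dt <- trials$decision_t
  per_trial <- purrr::map(seq_len(nrow(trials)), function(i) {
    n <- dt[i]
    if (n == 0L) {
      return(list(t = 0L, x = 0L, action = "go"))
    }
    xs <- abs(cumsum(cues_to_steps(trials$cues[i])[seq_len(n)]))
    list(t = seq_len(n), x = as.integer(xs),
         action = c(rep("wait", n - 1L), "go"))
  })
  n_rows <- vapply(per_trial, function(z) length(z$t), integer(1))
  out <- tibble(
    trials[rep(seq_len(nrow(trials)), n_rows), id_cols, drop = FALSE],
    t = unlist(purrr::map(per_trial, "t")),
    x = unlist(purrr::map(per_trial, "x")),
    action = unlist(purrr::map(per_trial, "action"))
  )
  class(out) <- c("waitgo_table", class(out))
  out
}

#' Fit the wait/go logistic regression
#'
#' Maximum-likelihood fit of
#' \deqn{\log \frac{P(A = \mathrm{go})}{P(A = \mathrm{wait})}
#'       = \beta_0 + \beta_T T + \beta_X X}
#' over the wait/go observation table (or the evidence-only model when
#' `include_time = FALSE`). On perfectly separable data — noiseless
#' threshold agents produce these — the unpenalised MLE diverges; the fit
#' then falls back to a weak ridge penalty (`ridge` on `beta_T`, `beta_X`,
#' never the intercept) and is flagged.
#'
#' @param table A [build_wait_go_table()] result.
#' @param include_time Include the time predictor `T`.
#' @param ridge Ridge penalty used only by the separation fallback.
#' @return A `waitgo_fit` with coefficient access via [tidy()] and a one-row
#'   summary (log-likelihood, `n_obs`, convergence) via [glance()].
#' @export
fit_waitgo_logistic <- function(table, include_time = TRUE, ridge = 1e-4) {
  stopifnot(is.data.frame(table))
  acts <- unique(table$action)
  if (length(acts) < 2L) {
    abort("the wait/go table must contain both actions to be fittable.")
  }
  y <- as.integer(table$action == "go")
  X <- if (include_time) {
    cbind(1, table$t, table$x)
  } else {
    cbind(1, table$x)
  }
  terms <- if (include_time) c("beta0", "betaT", "betaX") else
    c("beta0", "betaX")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
      if (grepl("algorithm did not converge", msg)) {
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- fit$coefficients
  converged <- isTRUE(fit$converged)
  if (sep || !converged || any(!is.finite(beta))) {
    pen <- function(b) {
      eta <- drop(X %*% b)
      nll <- sum(log1pexp(eta) - y * eta)
      nll + ridge * sum(b[-1]^2)
    }
    gr <- function(b) {
      eta <- drop(X %*% b)
      g <- drop(crossprod(X, plogis(eta) - y))
      g[-1] <- g[-1] + 2 * ridge * b[-1]
      g
    }
    opt <- optim(rep(0, ncol(X)), pen, gr, method = "BFGS",
                 control = list(maxit = 1000L, reltol = 1e-12))
    beta <- opt$par
    converged <- opt$convergence == 0L
    sep <- TRUE
  }
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1pexp(eta))
  structure(
    list(coef = setNames(as.double(beta), terms), log_likelihood = ll,
         n_obs = length(y), converged = converged, separation = sep,
         include_time = include_time),
    class = "waitgo_fit"
  )
}

#' @export
print.waitgo_fit <- function(x, ...) {
  cat("<waitgo_fit> ",
      if (x$include_time) "go ~ T + X" else "go ~ X",
      if (x$separation) "  [ridge fallback]" else "", "\n", sep = "")
  print(round(x$coef, 4))
  cat("logLik =", format(x$log_likelihood), "on", x$n_obs, "rows\n")
  invisible(x)
}

#' @describeIn fit_waitgo_logistic named coefficient vector.
#' @export
coef.waitgo_fit <- function(object, ...) object$coef

#' @describeIn fit_waitgo_logistic coefficients as a `term`/`estimate`
#'   tibble.
#' @param x,object A `waitgo_fit`.
#' @param ... Unused.
#' @export
tidy.waitgo_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @describeIn fit_waitgo_logistic one-row fit summary.
#' @export
glance.waitgo_fit <- function(x, ...) {
  tibble(
    log_likelihood = x$log_likelihood, n_obs = x$n_obs,
    df = length(x$coef), converged = x$converged,
    separation = x$separation
  )
}

#' The line of indifference of a wait/go fit
#'
#' The locus where the fitted wait and go probabilities are equal:
#' `X = -(betaT / betaX) T - beta0 / betaX`, whose gradient (evidence per
#' ISI unit) proxies the slope of the decision boundary. Slopes are reported
#' in degrees, `slope_deg = atan(gradient)`. When `|betaX|` falls below
#' `tol`, going is driven by time alone; the estimate is flagged
#' `time_dominated` and the slope saturates just inside +/-90 degrees.
#'
#' @param fit A `waitgo_fit` from [fit_waitgo_logistic()].
#' @param tol Magnitude of `betaX` below which the fit counts as
#'   time-dominated.
#' @return One-row tibble: `gradient`, `intercept`, `slope_deg`,
#'   `time_dominated`.
#' @examples
#' # beta = (0, 1, 1): line X = -T, slope -45 degrees
#' @export
line_of_indifference <- function(fit, tol = 1e-8) {
  stopifnot(inherits(fit, "waitgo_fit"))
  b0 <- fit$coef[["beta0"]]
  bT <- if (fit$include_time) fit$coef[["betaT"]] else 0
  bX <- fit$coef[["betaX"]]
  dominated <- abs(bX) < tol
  bX_eff <- if (dominated) tol * (if (bX < 0) -1 else 1) else bX
  gradient <- -bT / bX_eff
  slope <- atan(gradient) * 180 / pi
  cap <- 90 - 1e-6
  slope <- min(max(slope, -cap), cap)
  tibble(
    gradient = gradient,
    intercept = -b0 / bX_eff,
    slope_deg = slope,
    time_dominated = dominated
  )
}

#' Circular difference between two boundary slopes
#'
#' Slopes near +90 and -90 degrees both describe time-driven (nearly
#' vertical) boundaries, so slope differences are wrapped:
#' `delta = ((m_e - m_m + 90) mod 180) - 90`, confined to `[-90, 90)`.
#'
#' @param m_e,m_m Slopes in degrees (vectorised).
#' @return The wrapped difference in degrees.
#' @examples
#' circular_slope_difference(80, -80)  # -20
#' circular_slope_difference(10, -10)  # 20
#' @export
circular_slope_difference <- function(m_e, m_m) {
  ((m_e - m_m + 90) %% 180) - 90
}

#' Bootstrap confidence interval for the boundary slope
#'
#' Resamples whole trials with replacement, rebuilds the wait/go table,
#' refits the logistic model and recomputes the slope; returns percentile
#' bounds. Replicates whose fit does not converge are dropped (an error is
#' raised if more than half are lost).
#'
#' @param trials Trial-record tibble (already nondecision-stripped and
#'   condition-filtered).
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param level Confidence level (default 0.95 percentile interval).
#' @param ... Passed to [build_wait_go_table()].
#' @return One-row tibble: `slope_deg` (point estimate), `ci_low`,
#'   `ci_high`, `n_boot_ok`.
#' @export
bootstrap_slope_ci <- function(trials, n_boot = 1000L, level = 0.95, ...) {
  stopifnot(is.data.frame(trials))
  if (n_boot < 1L) abort("`n_boot` must be at least 1.")
  if (nrow(trials) < 2L) abort("need at least 2 trials to bootstrap.")
  point <- line_of_indifference(
    fit_waitgo_logistic(build_wait_go_table(trials, ...))
  )$slope_deg
  reps <- purrr::map_dbl(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(trials), replace = TRUE)
    tb <- build_wait_go_table(trials[idx, , drop = FALSE], ...)
    if (length(unique(tb$action)) < 2L) return(NA_real_)
    fit <- fit_waitgo_logistic(tb)
    if (!fit$converged) return(NA_real_)
    line_of_indifference(fit)$slope_deg
  })
  ok <- reps[!is.na(reps)]
  if (length(ok) < n_boot / 2) {
    abort("more than half of the bootstrap replicates failed to converge.")
  }
  qs <- quantile(ok, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble(slope_deg = point, ci_low = qs[1], ci_high = qs[2],
         n_boot_ok = length(ok))
}

#' Chance-performance exclusion test
#'
#' Two-sided exact binomial test of the number of correct choices against
#' chance (1/2). A participant whose accuracy cannot be distinguished from
#' chance (`p >= alpha`) is excluded.
#'
#' @param trials Trial-record tibble with a `correct` column (>= 1 trial).
#' @param alpha Significance level.
#' @return One-row tibble: `n`, `n_correct`, `p_value`, `excluded`.
#' @examples
#' binomial_exclusion_test(tibble::tibble(correct = rep(c(TRUE, FALSE), c(90, 10))))
#' @export
binomial_exclusion_test <- function(trials, alpha = 0.05) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) < 1L) abort("need at least 1 trial.")
  n <- nrow(trials)
  k <- sum(trials$correct)
  p <- binom.test(k, n, p = 0.5)$p.value
  tibble(n = n, n_correct = k, p_value = p, excluded = p >= alpha)
}
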