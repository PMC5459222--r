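# End-to-end cohort pipeline: simulate a preset experiment, estimate and
# strip nondecision lags, fit wait/go boundaries per condition, compare
# fixed vs time-varying models, and summarise the cohort.

fit_slots <- function() {
  tibble(
    fit = c("easy", "difficult", "mixed_easy", "mixed_difficult"),
    condition = c("easy", "difficult", "mixed", "mixed"),
    mixed_difficulty = c("all", "all", "easy", "difficult")
  )
}

na_fit_row <- function() {
  tibble(
    n_trials = NA_integer_, beta0 = NA_real_, betaT = NA_real_,
    betaX = NA_real_, log_likelihood = NA_real_, converged = NA,
    separation = NA, gradient = NA_real_, intercept = NA_real_,
    slope_deg = NA_real_, time_dominated = NA,
    ci_low = NA_real_, ci_high = NA_real_
  )
}

analyze_participant <- function(trials_p, nd_threshold = 0.75,
                                nd_max_lag = 10L, alpha = 0.05,
                                n_boot = 0L, margin = 2) {
  excl <- bind_rows(
    easy = binomial_exclusion_test(
      filter(trials_p, .data$condition == "easy"), alpha),
    mixed = binomial_exclusion_test(
      filter(trials_p, .data$condition == "mixed"), alpha),
    .id = "condition"
  )
  excluded <- any(excl$excluded)

  nd_est <- tryCatch(
    suppressWarnings(estimate_nondecision(
      filter(trials_p, .data$condition == "easy"),
      threshold = nd_threshold, max_lag = nd_max_lag
    )),
    error = function(e) NULL
  )
  nd <- if (is.null(nd_est)) 0L else nd_est$nd
  stripped <- strip_nondecision(trials_p, nd)

  rows <- purrr::pmap(fit_slots(), function(fit, condition, mixed_difficulty) {
    sub <- filter(stripped, .data$condition == !!condition)
    res <- tryCatch({
      tb <- build_wait_go_table(sub, mixed_difficulty = mixed_difficulty)
      f <- fit_waitgo_logistic(tb)
      li <- line_of_indifference(f)
      ci <- if (n_boot > 0L) {
        keep <- if (mixed_difficulty == "all") {
          sub
        } else {
          drifts <- sort(unique(sub$difficulty))
          want <- if (mixed_difficulty == "easy") max(drifts) else min(drifts)
          filter(sub, .data$difficulty == want)
        }
        tryCatch(bootstrap_slope_ci(keep, n_boot = n_boot),
                 error = function(e) tibble(ci_low = NA_real_,
                                            ci_high = NA_real_))
      } else {
        tibble(ci_low = NA_real_, ci_high = NA_real_)
      }
      tibble(
        n_trials = sum(tb$action == "go"),
        beta0 = f$coef[["beta0"]], betaT = f$coef[["betaT"]],
        betaX = f$coef[["betaX"]],
        log_likelihood = f$log_likelihood, converged = f$converged,
        separation = f$separation,
        gradient = li$gradient, intercept = li$intercept,
        slope_deg = li$slope_deg, time_dominated = li$time_dominated,
        ci_low = ci$ci_low, ci_high = ci$ci_high
      )
    }, error = function(e) na_fit_row())
    mutate(res, fit = fit, .before = 1L)
  }) |> bind_rows()

  comparisons <- purrr::pmap(fit_slots(), function(fit, condition,
                                                   mixed_difficulty) {
    sub <- filter(stripped, .data$condition == !!condition)
    res <- tryCatch({
      tb <- build_wait_go_table(sub, mixed_difficulty = mixed_difficulty)
      compare_boundary_models(tb, margin = margin)
    }, error = function(e) {
      tibble(bic_fixed = NA_real_, bic_varying = NA_real_,
             delta_bic = NA_real_, post_prob_varying = NA_real_,
             winner = NA_character_)
    })
    mutate(as_tibble(res), fit = fit, .before = 1L)
  }) |> bind_rows()

  list(
    fits = mutate(rows, nd = nd,
                  nd_saturated = !is.null(nd_est) && nd_est$saturated,
                  excluded = excluded),
    comparisons = mutate(comparisons, excluded = excluded)
  )
}

#' Run a full simulated experiment
#'
#' Simulates a cohort on one of the [experiment_preset()] parameter sets and
#' runs the complete analysis chain: chance-level exclusion, nondecision-lag
#' estimation on the easy games, lag stripping, per-condition wait/go
#' logistic fits (easy, difficult, and the easy and difficult trial subsets
#' of mixed games), lines of indifference, optional bootstrap intervals, and
#' fixed-versus-varying model comparison, ending in a cohort summary.
#'
#' By default every participant is a rise-to-threshold agent using the
#' reward-rate-optimal boundary of each condition's task (computed by
#' [solve_optimal_policy()]), integrating with internal noise and a one-cue
#' nondecision lag.
#'
#' @param name Preset name, see [experiment_preset()].
#' @param n_participants Cohort size (default 24).
#' @param agent `"optimal"` (default), a single [agent_spec()], or a
#'   function `function(participant)` as in [simulate_cohort()].
#' @param sigma_internal,nd_samples Noise and lag given to the optimal
#'   agents (ignored when `agent` is supplied explicitly).
#' @param n_boot Bootstrap replicates per fit (0 skips the intervals).
#' @param nd_threshold,nd_max_lag Passed to [estimate_nondecision()].
#' @param alpha Exclusion-test level.
#' @param margin BIC ambiguity margin.
#' @param t_max Horizon for the optimal-policy solve.
#' @param keep_trials Keep the raw trial table in the result.
#' @return A list of class `waitgo_run`: `name`, `preset`, `participants`
#'   (per-participant, per-condition fit tibble), `comparisons` (BIC
#'   table), `cohort` (see [summarize_cohort()]), `boundaries`
#'   (per-condition optimal boundaries, when `agent = "optimal"`), and
#'   optionally `trials`.
#' @examples
#' \donttest{
#' set.seed(1)
#' run <- run_experiment_preset("exp1", n_participants = 4)
#' run$cohort$paired
#' }
#' @export
run_experiment_preset <- function(name, n_participants = 24L,
                                  agent = "optimal",
                                  sigma_internal = 0.5, nd_samples = 1L,
                                  n_boot = 0L, nd_threshold = 0.75,
                                  nd_max_lag = 10L, alpha = 0.05,
                                  margin = 2, t_max = 100L,
                                  keep_trials = FALSE) {
  preset <- experiment_preset(name)
  boundaries <- NULL
  if (identical(agent, "optimal")) {
    boundaries <- purrr::map(preset$tasks, function(task) {
      extract_boundary(solve_optimal_policy(task, t_max = t_max))
    })
    agents <- purrr::map(boundaries, function(b) {
      agent_spec("threshold", boundary = b, sigma_internal = sigma_internal,
                 nd_samples = nd_samples)
    })
    sampler <- function(p) agents
  } else if (inherits(agent, "waitgo_agent") || is.function(agent)) {
    sampler <- agent
  } else {
    abort("`agent` must be \"optimal\", an agent_spec or a function.")
  }

  trials <- simulate_cohort(n_participants, sampler, preset$tasks,
                            preset$durations, n_blocks = preset$n_blocks)

  per <- purrr::map(
    split(trials, trials$participant),
    analyze_participant,
    nd_threshold = nd_threshold, nd_max_lag = nd_max_lag,
    alpha = alpha, n_boot = n_boot, margin = margin
  )
  participants <- bind_rows(purrr::map(per, "fits"), .id = "participant") |>
    mutate(participant = as.integer(.data$participant))
  comparisons <- bind_rows(purrr::map(per, "comparisons"),
                           .id = "participant") |>
    mutate(participant = as.integer(.data$participant))

  pair <- if (name == "exp3") c("difficult", "mixed_difficult") else
    c("easy", "mixed_easy")
  cohort <- tryCatch(summarize_cohort(participants, pair = pair),
                     error = function(e) NULL)

  out <- list(
    name = name, preset = preset, participants = participants,
    comparisons = comparisons, cohort = cohort, boundaries = boundaries,
    pair = pair
  )
  if (keep_trials) out$trials <- trials
  class(out) <- "waitgo_run"
  out
}

#' @export
print.waitgo_run <- function(x, ...) {
  cat("<waitgo_run> ", x$name, ": ",
      length(unique(x$participants$participant)), " participants\n", sep = "")
  if (!is.null(x$cohort)) {
    cat("  paired comparison (", paste(x$pair, collapse = " vs "), "):\n",
        sep = "")
    print(x$cohort$paired)
  }
  invisible(x)
}

#' Summarise a cohort of fitted participants
#'
#' Per-condition mean slopes over included participants, the paired
#' circular slope difference for a chosen pair of fit conditions, and a
#' paired t-test on those differences (reported as `NA` when the
#' differences have no variance).
#'
#' @param participants The `participants` tibble of a [run_experiment_preset()]
#'   result (or any tibble with `participant`, `fit`, `slope_deg`,
#'   `excluded`).
#' @param pair Character pair of fit conditions, difference taken as
#'   `circular_slope_difference(pair[1], pair[2])` per participant.
#' @return A list of class `waitgo_cohort_summary`: `by_condition` (fit, n,
#'   mean/sd slope), `paired` (n, mean_delta, t, df, p_value), and
#'   `n_excluded`.
#' @export
summarize_cohort <- function(participants, pair = c("easy", "mixed_easy")) {
  stopifnot(is.data.frame(participants), length(pair) == 2L)
  kept <- filter(participants, !.data$excluded, !is.na(.data$slope_deg))
  if (length(unique(kept$participant)) < 2L) {
    abort("fewer than 2 included participants: nothing to summarise.")
  }
  by_condition <- kept |>
    group_by(.data$fit) |>
    summarise(n = dplyr::n(), mean_slope = mean(.data$slope_deg),
              sd_slope = sd(.data$slope_deg), .groups = "drop")
  wide <- kept |>
    filter(.data$fit %in% pair) |>
    select("participant", "fit", "slope_deg") |>
    tidyr::pivot_wider(names_from = "fit", values_from = "slope_deg") |>
    tidyr::drop_na()
  if (nrow(wide) < 2L) {
    abort("fewer than 2 participants with both paired conditions.")
  }
  delta <- circular_slope_difference(wide[[pair[1]]], wide[[pair[2]]])
  tt <- tryCatch(t.test(delta), error = function(e) NULL)
  paired <- tibble(
    pair_a = pair[1], pair_b = pair[2], n = length(delta),
    mean_delta = mean(delta),
    t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
    p_value = if (is.null(tt)) NA_real_ else tt$p.value
  )
  structure(
    list(by_condition = by_condition, paired = paired,
         n_excluded = length(unique(
           participants$participant[participants$excluded]))),
    class = "waitgo_cohort_summary"
  )
}

#' @export
print.waitgo_cohort_summary <- function(x, ...) {
  cat("<waitgo_cohort_summary> (", x$n_excluded, " excluded)\n", sep = "")
  print(x$by_condition)
  print(x$paired)
  invisible(x)
}
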