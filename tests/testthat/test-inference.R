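test_that("nondecision lags are recovered exactly for noiseless agents", {
  task <- task_config(0.2, d_correct = 15, d_incorrect = 50)
  set.seed(101)
  for (lag in c(0L, 2L)) {
    ag <- agent_spec("threshold", boundary = 3, nd_samples = lag)
    trs <- sim_trials(ag, task, 400)
    est <- estimate_nondecision(trs)
    expect_equal(est$nd, lag)
    expect_false(est$saturated)
  }
  expect_error(estimate_nondecision(sim_trials(
    agent_spec("threshold", boundary = 3), task, 5
  )), "at least")
})

test_that("stripping the lag rewinds the decision state", {
  trials <- tibble::tibble(
    condition = "easy", difficulty = 0.2, world = "up",
    response = "up", correct = TRUE, decision_t = 3L, cues = "+++",
    trial_id = 1L
  )
  expect_identical(strip_nondecision(trials, 0)$cues, "+++")
  st <- strip_nondecision(trials, 1)
  expect_equal(st$decision_t, 2L)
  expect_equal(st$cues, "++")
  tb <- build_wait_go_table(st)
  expect_equal(tb$t[tb$action == "go"], 2L)
  expect_equal(tb$x[tb$action == "go"], 2L)

  short <- dplyr::mutate(trials, decision_t = 1L, cues = "+")
  dropped <- strip_nondecision(short, 1)
  expect_equal(nrow(dropped), 0L)
  expect_equal(attr(dropped, "n_dropped"), 1L)
})

test_that("the wait/go table enumerates every opportunity once", {
  trials <- tibble::tibble(
    condition = "easy", difficulty = 0.2, world = "up", response = "up",
    correct = TRUE, decision_t = 3L, cues = "+-+", trial_id = 1L
  )
  tb <- build_wait_go_table(trials)
  expect_equal(tb$t, 1:3)
  expect_equal(tb$x, c(1L, 0L, 1L))
  expect_equal(tb$action, c("wait", "wait", "go"))

  guess <- dplyr::mutate(trials, decision_t = 0L, cues = "")
  tg <- build_wait_go_table(guess)
  expect_equal(nrow(tg), 1L)
  expect_equal(unlist(tg[, c("t", "x")]), c(t = 0L, x = 0L))
  expect_equal(tg$action, "go")

  # folded evidence: a mirrored trial gives the same table
  down <- dplyr::mutate(trials, cues = "-+-", response = "down",
                        world = "down")
  expect_equal(build_wait_go_table(down)[, c("t", "x", "action")],
               tb[, c("t", "x", "action")])
})

test_that("mixed-condition filtering keeps the requested difficulty", {
  trials <- tibble::tibble(
    condition = "mixed", difficulty = rep(c(0.22, 0), each = 4),
    world = "up", response = "up", correct = TRUE,
    decision_t = 2L, cues = "++", trial_id = 1:8
  )
  easy_tb <- build_wait_go_table(trials)
  expect_true(all(easy_tb$difficulty == 0.22))
  expect_equal(sum(easy_tb$action == "go"), 4L)
  diff_tb <- build_wait_go_table(trials, mixed_difficulty = "difficult")
  expect_true(all(diff_tb$difficulty == 0))
  all_tb <- build_wait_go_table(trials, easy_only_in_mixed = FALSE)
  expect_equal(sum(all_tb$action == "go"), 8L)
})

test_that("logistic coefficients are recovered from a known generator", {
  set.seed(111)
  truth <- c(-4, 0.2, 1)
  ag <- agent_spec("probabilistic", betas = truth)
  trs <- sim_trials(ag, task_easy(), 2500)
  tb <- build_wait_go_table(trs)
  fit <- fit_waitgo_logistic(tb)
  expect_true(fit$converged)
  expect_false(fit$separation)
  # percentile bootstrap over trials must cover the generating values
  set.seed(112)
  boots <- t(replicate(60, {
    idx <- sample.int(nrow(trs), replace = TRUE)
    coef(fit_waitgo_logistic(build_wait_go_table(trs[idx, ])))
  }))
  for (k in 1:3) {
    qs <- quantile(boots[, k], c(0.005, 0.995))
    expect_gte(truth[k], qs[[1]])
    expect_lte(truth[k], qs[[2]])
  }

  # null recovery: a generator that ignores evidence
  set.seed(113)
  ag0 <- agent_spec("probabilistic", betas = c(-2.5, 0.3, 0))
  tb0 <- build_wait_go_table(sim_trials(ag0, task_easy(), 1500))
  f0 <- fit_waitgo_logistic(tb0)
  expect_lt(abs(f0$coef[["betaX"]]), 0.25)

  # nested models: dropping time cannot raise the likelihood
  f2 <- fit_waitgo_logistic(tb, include_time = FALSE)
  expect_lte(f2$log_likelihood, fit$log_likelihood)
  expect_error(fit_waitgo_logistic(tb[tb$action == "go", ]), "both actions")
})

test_that("separable data fall back to the flagged ridge fit", {
  set.seed(121)
  ag <- agent_spec("threshold", boundary = 4)
  tb <- build_wait_go_table(sim_trials(ag, task_easy(), 250))
  fit <- fit_waitgo_logistic(tb)
  expect_true(fit$separation)
  li <- line_of_indifference(fit)
  # flat noiseless boundary: indifference sits between 3 and 4
  expect_lt(abs(li$slope_deg), 6)
  expect_gt(li$intercept, 2.5)
  expect_lt(li$intercept, 4.5)
})

test_that("the line of indifference follows the fitted coefficients", {
  mk <- function(coefs, include_time = TRUE) {
    structure(list(coef = coefs, log_likelihood = -1, n_obs = 10,
                   converged = TRUE, separation = FALSE,
                   include_time = include_time),
              class = "waitgo_fit")
  }
  li <- line_of_indifference(mk(c(beta0 = -3, betaT = 0, betaX = 1)))
  expect_equal(li$slope_deg, 0)
  expect_equal(li$intercept, 3)
  li <- line_of_indifference(mk(c(beta0 = 0, betaT = 1, betaX = 1)))
  expect_equal(li$slope_deg, -45)
  li <- line_of_indifference(mk(c(beta0 = -1, betaT = 2, betaX = 1e-12)))
  expect_true(li$time_dominated)
  expect_lt(li$slope_deg, -89)
})

test_that("circular slope differences wrap into [-90, 90)", {
  expect_equal(circular_slope_difference(0, 0), 0)
  expect_equal(circular_slope_difference(80, -80), -20)
  expect_equal(circular_slope_difference(10, -10), 20)
  grid <- expand.grid(a = seq(-89.5, 90, by = 4.5),
                      b = seq(-89.5, 90, by = 4.5))
  d <- circular_slope_difference(grid$a, grid$b)
  expect_true(all(d >= -90 & d < 90))
})

test_that("bootstrap intervals behave on degenerate and noisy data", {
  same <- tibble::tibble(
    condition = "easy", difficulty = 0.2, world = "up", response = "up",
    correct = TRUE, decision_t = 3L,
    cues = rep(c("+++", "+-+", "++-+"), 4),
    trial_id = 1:12
  )
  same$decision_t <- nchar(same$cues)
  expect_error(bootstrap_slope_ci(same, n_boot = 0), "at least 1")
  one <- same[rep(1, 10), ]
  one$trial_id <- 1:10
  expect_error(bootstrap_slope_ci(one[1, ], n_boot = 10), "at least 2")
  # identical trials: every resample refits the same data, zero-width CI
  ci0 <- bootstrap_slope_ci(one, n_boot = 25)
  expect_equal(ci0$ci_low, ci0$ci_high)
  expect_equal(ci0$ci_low, ci0$slope_deg, tolerance = 1e-6)

  set.seed(131)
  ag <- agent_spec("probabilistic", betas = c(-4, 0.2, 1))
  trs <- sim_trials(ag, task_easy(), 400)
  ci <- bootstrap_slope_ci(trs, n_boot = 120)
  expect_lte(ci$ci_low, ci$slope_deg)
  expect_gte(ci$ci_high, ci$slope_deg)
  expect_gte(ci$n_boot_ok, 60)
})

test_that("bootstrap intervals cover a known generating slope", {
  # generator with betas (-4, 0.4, 1): true line slope -21.8 degrees
  truth <- atan(-0.4) * 180 / pi
  set.seed(141)
  covered <- vapply(1:5, function(i) {
    trs <- sim_trials(agent_spec("probabilistic", betas = c(-4, 0.4, 1)),
                      task_easy(), 350)
    ci <- bootstrap_slope_ci(trs, n_boot = 150)
    ci$ci_low <= truth && truth <= ci$ci_high
  }, logical(1))
  expect_gte(sum(covered), 3)
})

test_that("the chance-level exclusion test follows the binomial law", {
  strong <- tibble::tibble(correct = rep(c(TRUE, FALSE), c(90, 10)))
  res <- binomial_exclusion_test(strong)
  expect_false(res$excluded)
  expect_equal(res$p_value, binom.test(90, 100, 0.5)$p.value)
  chance <- tibble::tibble(correct = rep(c(TRUE, FALSE), 50))
  expect_true(binomial_exclusion_test(chance)$excluded)
  expect_error(binomial_exclusion_test(chance[0, ]), "at least 1")
})
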