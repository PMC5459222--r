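test_that("cue generation matches its Bernoulli law", {
  expect_identical(generate_cues(1, 5), rep(1L, 5))
  expect_identical(generate_cues(0, 4), rep(-1L, 4))
  expect_length(generate_cues(0.5, 0), 0L)
  set.seed(5)
  n <- 1e5
  se <- 2 * sqrt(0.7 * 0.3 / n)
  expect_lt(abs(mean(generate_cues(0.7, n)) - 0.4), 3 * se)
  expect_lt(abs(mean(generate_cues(0.5, n))), 3 * 2 * sqrt(0.25 / n))
  expect_error(generate_cues(1.2, 5))
})

test_that("deterministic threshold trials behave exactly", {
  task <- task_config(0.5, d_correct = 5, d_incorrect = 5)  # u = 1
  ag <- agent_spec("threshold", boundary = 3)
  tr <- simulate_trial(ag, task, difficulty = 0.5, world = "up")
  expect_equal(tr$decision_t, 3L)
  expect_equal(tr$response, "up")
  expect_true(tr$correct)
  expect_equal(tr$cues, "+++")

  # immediate-guess boundary: decision at the nondecision lag, coin response
  ag0 <- agent_spec("threshold", boundary = 0, nd_samples = 2)
  set.seed(9)
  trs <- dplyr::bind_rows(lapply(1:300, function(i) {
    simulate_trial(ag0, task_config(0, d_correct = 5, d_incorrect = 5),
                   world = "up")
  }))
  expect_true(all(trs$decision_t == 2L))
  expect_true(all(nchar(trs$cues) == 2L))
  expect_lt(abs(mean(trs$response == "up") - 0.5), 3 * sqrt(0.25 / 300))
})

test_that("the nondecision lag appends cues after the internal decision", {
  task <- task_config(0.5, d_correct = 5, d_incorrect = 5)
  ag <- agent_spec("threshold", boundary = 2, nd_samples = 3)
  tr <- simulate_trial(ag, task, difficulty = 0.5, world = "down")
  expect_equal(tr$decision_t, 5L)          # 2 to threshold + 3 lag
  expect_equal(nchar(tr$cues), 5L)
  expect_equal(tr$response, "down")
})

test_that("a stiff probabilistic boundary approximates the threshold rule", {
  task <- task_easy()
  # p(go) ~ step at |x| = 3: beta0 = -50 * 2.5, betaX = 50, betaT = 0
  stiff <- agent_spec("probabilistic", betas = c(-125, 0, 50))
  hard <- agent_spec("threshold", boundary = 3)
  set.seed(21)
  a <- sim_trials(stiff, task, 1500)
  b <- sim_trials(hard, task, 1500)
  se_dt <- sqrt(var(a$decision_t) / 1500 + var(b$decision_t) / 1500)
  expect_lt(abs(mean(a$decision_t) - mean(b$decision_t)), 3 * se_dt)
  se_pc <- sqrt(0.25 / 1500 + 0.25 / 1500)
  expect_lt(abs(mean(a$correct) - mean(b$correct)), 3 * se_pc)
})

test_that("blocks respect the duration budget and mixture weights", {
  expect_equal(nrow(simulate_block(agent_spec("threshold", boundary = 3),
                                   task_easy(), duration = 0)), 0L)
  set.seed(31)
  task <- task_mixed()
  ag <- agent_spec("threshold", boundary = 3, sigma_internal = 0.5)
  bl <- simulate_block(ag, task, duration = 3000, condition = "mixed")
  delays <- ifelse(bl$correct, task$d_correct, task$d_incorrect)
  used <- sum(bl$decision_t + delays)
  expect_lte(used, 3000 + max(delays))
  expect_gt(nrow(bl), 20)
  expect_lt(abs(mean(bl$difficulty == 0.22) - 0.5),
            3 * sqrt(0.25 / nrow(bl)))
})

test_that("block reward accrual is consistent with the exact reward rate", {
  set.seed(41)
  task <- task_easy()
  ag <- agent_spec("threshold", boundary = 3)  # the optimal flat boundary
  rho <- evaluate_reward_rate(
    policy_from_linear_boundary(linear_boundary(3), 100), task
  )
  duration <- 2000
  rewards <- replicate(40, {
    sum(simulate_block(ag, task, duration)$correct)
  })
  se <- sd(rewards) / sqrt(length(rewards))
  expect_lt(abs(mean(rewards) - rho * duration), 3 * se + 1)
})

test_that("cohorts are reproducible and record per-participant seeds", {
  tasks <- list(easy = task_easy())
  ag <- agent_spec("threshold", boundary = 3, sigma_internal = 0.5)
  set.seed(77)
  c1 <- simulate_cohort(3, ag, tasks, c(easy = 500), n_blocks = 1)
  set.seed(77)
  c2 <- simulate_cohort(3, ag, tasks, c(easy = 500), n_blocks = 1)
  expect_identical(c1, c2)
  expect_equal(dplyr::n_distinct(c1$seed), 3L)
  expect_setequal(unique(c1$participant), 1:3)
})

test_that("trial-to-trial drift variability stays a valid Bernoulli", {
  set.seed(51)
  ag <- agent_spec("threshold", boundary = 2, sigma_drift = 0.35)
  trs <- dplyr::bind_rows(lapply(1:200, function(i) {
    simulate_trial(ag, task_easy(), difficulty = 0.22)
  }))
  expect_true(all(trs$decision_t >= 2))
  expect_true(all(grepl("^[+-]+$", trs$cues)))
})

test_that("agent specification is validated", {
  expect_error(agent_spec("threshold"), "boundary")
  expect_error(agent_spec("probabilistic", betas = c(1, 2)), "betas")
  expect_error(agent_spec("threshold", boundary = 3, p_attend = 0))
  expect_error(agent_spec("threshold", boundary = 3, nd_samples = -1))
})
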