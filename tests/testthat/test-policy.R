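# Per-parity boundary values over the region where the policy ever waits;
# the integer lattice makes a constant threshold alternate between two
# adjacent integers across odd/even t.
theta_by_parity <- function(boundary, parity, t_hi) {
  th <- boundary$theta[boundary$t <= t_hi & boundary$t %% 2 == parity]
  th[!is.na(th)]
}

last_wait_time <- function(policy) {
  tt <- tidy(policy)
  max(c(-1L, tt$t[tt$action == "wait"]))
}

test_that("zero drift makes immediate guessing optimal", {
  task <- task_config(0, d_correct = 70, d_incorrect = 70)
  pol <- solve_optimal_policy(task, t_max = 50)
  b <- extract_boundary(pol)
  expect_true(all(b$theta == 0))
  expect_equal(pol$gain, 0.5 / 70, tolerance = 1e-8)
})

test_that("single-difficulty boundaries are constant over the wait region", {
  pol <- solve_optimal_policy(task_config(0.2, d_correct = 70,
                                          d_incorrect = 70), t_max = 80)
  b <- extract_boundary(pol)
  # truncation distorts the boundary close to the forced-go horizon; the
  # constancy claim is about the stationary region
  t_hi <- min(last_wait_time(pol), 80 - 15)
  expect_gt(t_hi, 10)
  for (par in 0:1) {
    th <- theta_by_parity(b, par, t_hi)
    expect_length(unique(th), 1L)
  }
})

test_that("optimal boundary height is nonmonotone in difficulty", {
  d <- 70
  # boundary height where the frontier first enters the reachable cone
  # (away from the truncation horizon, which forces a collapse)
  th_at <- function(eps, t_max = 80) {
    pol <- solve_optimal_policy(task_config(eps, d_correct = d,
                                            d_incorrect = d), t_max = t_max)
    b <- extract_boundary(pol)
    b$theta[!is.na(b$theta)][1]
  }
  expect_gte(th_at(0.05), th_at(0.45))
  expect_equal(th_at(0), 0)
  expect_gt(th_at(0.2), 0)
})

test_that("mixing in an impossible difficulty collapses the boundary", {
  pol <- solve_optimal_policy(task_mixed(), t_max = 80)
  b <- extract_boundary(pol)
  for (par in 0:1) {
    th <- theta_by_parity(b, par, 80)
    expect_true(all(diff(th) <= 0))
  }
  expect_equal(min(b$theta, na.rm = TRUE), 0)
})

test_that("mixing two moderate difficulties raises the boundary", {
  pol <- solve_optimal_policy(
    task_config(c(0.4, 0.1), d_correct = 50, d_incorrect = 50), t_max = 80
  )
  b <- extract_boundary(pol)
  t_hi <- min(last_wait_time(pol), 80 - 15)
  for (par in 0:1) {
    th <- theta_by_parity(b, par, t_hi)
    expect_true(all(diff(th) >= 0))
  }
})

test_that("the optimal action map ignores the correct-trial delay", {
  pols <- lapply(c(10, 25, 40), function(dc) {
    solve_optimal_policy(task_config(c(0.22, 0), d_correct = dc,
                                     d_incorrect = 50), t_max = 50)
  })
  expect_identical(pols[[1]]$go, pols[[2]]$go)
  expect_identical(pols[[2]]$go, pols[[3]]$go)
})

test_that("the policy is invariant to enlarging the horizon", {
  task <- task_config(0.2, d_correct = 70, d_incorrect = 70)
  p1 <- solve_optimal_policy(task, t_max = 40)
  p2 <- solve_optimal_policy(task, t_max = 80)
  # actions agree away from the truncation horizon, and the gain converges
  # (the horizon only contributes an O(P(reach t_max)) bias)
  expect_identical(p1$go[1:26, 1:81], p2$go[1:26, 41:121])
  expect_equal(p1$gain, p2$gain, tolerance = 1e-3)
})

test_that("the solved gain matches exhaustive boundary enumeration", {
  # tiny horizon: every boundary-shaped policy theta: {0..t} -> {0..t_max+1}
  task <- task_config(0.2, d_correct = 5, d_incorrect = 5)
  t_max <- 4
  heights <- 0:(t_max + 1)
  grids <- expand.grid(rep(list(heights), t_max + 1))
  rates <- apply(grids, 1, function(th) {
    b <- tibble::tibble(t = 0:t_max, theta = as.double(th))
    class(b) <- c("waitgo_boundary", class(b))
    evaluate_reward_rate(policy_from_linear_boundary(b, t_max), task)
  })
  pol <- solve_optimal_policy(task, t_max = t_max)
  expect_equal(pol$gain, max(rates), tolerance = 1e-6)
})

test_that("degenerate rewards give a zero-gain all-go policy", {
  task <- task_config(0.2, d_correct = 10, d_incorrect = 10, reward = 0)
  pol <- solve_optimal_policy(task, t_max = 30)
  expect_equal(pol$gain, 0, tolerance = 1e-12)
  expect_true(all(extract_boundary(pol)$theta == 0))
})
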