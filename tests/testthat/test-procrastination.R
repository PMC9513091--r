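test_that("net value curve matches the discounted benefit-cost difference", {
  task <- procrastination_task(100, 85, 0.05, 0.2, theta = 0.5, deadline = 30)
  v <- net_value_curve(task)
  expect_length(v, 31)
  expect_equal(v[1], 15)                        # day 0: R - E
  expect_equal(v[2], 100 / 1.05 - 85 / 1.2)     # day 1
  # equal rates: the whole curve is (R - E)/(1 + k d)
  t2 <- procrastination_task(100, 85, 0.1, 0.1, deadline = 10)
  expect_equal(net_value_curve(t2), 15 / (1 + 0.1 * (0:10)))
})

test_that("static model: completion is immediate whenever k_R >= k_E", {
  set.seed(31)
  for (i in 1:200) {
    ks <- sort(runif(2, 0, 0.5))               # k_R >= k_E
    task <- random_task(k_R = ks[2], k_E = ks[1])
    expect_identical(static_optimal_delay(task), 0L)
  }
})

test_that("static model: the reference task peaks on day 8", {
  task <- procrastination_task(100, 85, 0.05, 0.2, deadline = 30)
  # independent check: exhaustive evaluation of the closed-form curve
  v <- 100 / (1 + 0.05 * (0:30)) - 85 / (1 + 0.2 * (0:30))
  expect_identical(which.max(v) - 1L, 8L)
  expect_identical(static_optimal_delay(task), 8L)
})

test_that("static softmax readout is uniform at theta = 0", {
  task <- procrastination_task(50, 30, 0.1, 0.2, theta = 0, deadline = 12)
  dist <- static_optimal_delay(task, mode = "softmax")
  expect_equal(dist$pmf, rep(1 / 13, 13))
})

test_that("dynamic daily probability has the stated closed forms", {
  task <- procrastination_task(50, 30, 0.06, 0.15, theta = 0, deadline = 30)
  # theta = 0: uniform softmax over the remaining horizon
  expect_equal(dynamic_daily_prob(task, 0), 1 / 31)
  expect_equal(dynamic_daily_prob(task, 10), 1 / 21)
  # deadline day: completion is certain
  expect_identical(dynamic_daily_prob(task, 30), 1)
  # a flat value curve (zero rates) gives 1/(D - d + 1) at any theta
  flat0 <- procrastination_task(50, 25, 0, 0, theta = 3, deadline = 8)
  expect_equal(dynamic_daily_prob(flat0, 0:8), 1 / (9:1))
  expect_error(dynamic_daily_prob(task, 31), "0, deadline")
})

test_that("completion distribution satisfies its probability invariants", {
  set.seed(17)
  for (i in 1:50) {
    task <- random_task(theta = runif(1, 0, 3))
    dist <- dynamic_completion_distribution(task)
    expect_true(all(dist$pmf >= 0))
    expect_equal(sum(dist$pmf), 1, tolerance = 1e-12)
    expect_true(all(diff(dist$cdf) >= -1e-15))
    expect_equal(dist$cdf[31], 1, tolerance = 1e-12)
    expect_identical(dist$daily_prob[31], 1)
    expect_equal(dist$expected_delay, sum(0:30 * dist$pmf))
  }
})

test_that("indifferent agents complete uniformly over the horizon", {
  task <- procrastination_task(10, 5, 0.1, 0.1, theta = 0, deadline = 2)
  dist <- dynamic_completion_distribution(task)
  expect_equal(dist$pmf, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(dist$expected_delay, 1, tolerance = 1e-12)
})

test_that("greedy agents postpone to the limit dictated by the value curve", {
  # for the reference task, doing it now is never optimal within any
  # remaining horizon, so a near-deterministic agent waits out the deadline
  late <- procrastination_task(100, 85, 0.05, 0.2, theta = 200, deadline = 30)
  expect_equal(dynamic_completion_distribution(late)$expected_delay, 30,
               tolerance = 1e-6)
  # when now is strictly best, a near-deterministic agent acts immediately
  early <- procrastination_task(100, 40, 0.3, 0.05, theta = 200, deadline = 30)
  expect_equal(dynamic_completion_distribution(early)$expected_delay, 0,
               tolerance = 1e-6)
})

test_that("expected delay is nondecreasing in the deadline", {
  for (D in list(c(5, 10), c(10, 20), c(20, 30))) {
    t1 <- procrastination_task(50, 30, 0.05, 0.2, theta = 0.5, deadline = D[1])
    t2 <- procrastination_task(50, 30, 0.05, 0.2, theta = 0.5, deadline = D[2])
    expect_lte(dynamic_completion_distribution(t1)$expected_delay,
               dynamic_completion_distribution(t2)$expected_delay + 1e-12)
  }
})

test_that("delay likelihood scores the pmf at the observed day", {
  task <- procrastination_task(10, 5, 0.1, 0.1, theta = 0, deadline = 2)
  expect_equal(delay_loglik(task, 1, model = "dynamic"), log(1 / 3),
               tolerance = 1e-12)
  # deadline-day observations always have positive mass
  t30 <- procrastination_task(50, 30, 0.05, 0.25, theta = 0.5, deadline = 30)
  expect_gt(delay_loglik(t30, 30, model = "dynamic"), -Inf)
  expect_error(delay_loglik(t30, 31), "0, deadline")
  # the degenerate argmax readout cannot be used as a likelihood
  expect_error(delay_loglik(t30, 3, model = "static_argmax"))
})

test_that("analytic expected delay agrees with simulated agents", {
  set.seed(23)
  for (i in 1:4) {
    task <- random_task(theta = runif(1, 0, 1))
    dist <- dynamic_completion_distribution(task, normalize = "none")
    sim <- simulate_completion(task, 20000, normalize = "none", seed = 40 + i)
    se <- sd(sim) / sqrt(length(sim))
    expect_lt(abs(mean(sim) - dist$expected_delay), 4 * se + 1e-9)
  }
})

test_that("duration grid marginalizes correctly and handles n = 1", {
  g1 <- simulate_duration_grid(n_samples = 1, seed = 9)
  expect_equal(nrow(g1), 1)
  # the single sampled task's expected delay is reproduced exactly
  draws <- with(list(), {
    set.seed(9)
    list(k_R = runif(1, 0, 0.5), k_E = runif(1, 0, 0.5),
         R = runif(1, 40, 60), E = runif(1, 20, 40))
  })
  task <- procrastination_task(draws$R, draws$E, draws$k_R, draws$k_E, 0.5, 30)
  expect_equal(g1$mean_duration,
               dynamic_completion_distribution(task, "none")$expected_delay)
  # static grid: zero duration wherever k_R >= k_E
  gs <- simulate_duration_grid(n_samples = 400, model = "static", seed = 10)
  upper <- gs[gs$k_R_mid > gs$k_E_mid, ]
  expect_true(all(upper$mean_duration == 0))
})

test_that("fitting the completion temperature prefers plausible delays", {
  task <- procrastination_task(50, 30, 0.05, 0.25, theta = 0.5, deadline = 30)
  obs <- 28  # a late return, typical of the dynamic process here
  fit <- fit_delay_model(task, obs, model = "dynamic", n_restarts = 3, seed = 2)
  expect_length(fit$par, 1)
  expect_true(is.finite(fit$log_evidence))
})
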