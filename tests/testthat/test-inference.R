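test_that("MAP estimation solves the quadratic problem in closed form", {
  # Gaussian log-"likelihood": the posterior is conjugate, so the MAP and
  # the Laplace evidence both have exact closed forms
  cc <- c(1.3, -0.7); s <- c(0.5, 2)
  m <- c(0, 0.5); sd <- c(1, 1.5)
  ll <- function(x) -0.5 * sum((x - cc)^2 / s^2)
  fit <- fit_map(ll, m, sd, n_restarts = 3, seed = 1)
  post_var <- 1 / (1 / s^2 + 1 / sd^2)
  post_mean <- post_var * (cc / s^2 + m / sd^2)
  expect_equal(unname(fit$par), post_mean, tolerance = 1e-5)
  exact_ev <- sum(0.5 * log(post_var) - log(sd) -
                    (cc - m)^2 / (2 * (s^2 + sd^2)))
  expect_equal(fit$log_evidence, exact_ev, tolerance = 1e-5)
  expect_true(fit$converged)
})

test_that("with no data the MAP is the prior mean", {
  fit <- fit_map(function(x) 0, c(0.3, -1), c(1, 2), n_restarts = 2, seed = 2)
  expect_equal(unname(fit$par), c(0.3, -1), tolerance = 1e-5)
})

test_that("a parameter-free model has evidence equal to its log-likelihood", {
  fit <- fit_map(function(x) -12.34, numeric(0), numeric(0), seed = 1)
  expect_identical(fit$log_evidence, -12.34)
  expect_identical(log_evidence(fit), -12.34)
})

test_that("unneeded extra parameters lower the evidence of a nested fit", {
  # complexity penalty: when a single shared rate generated the data, the
  # category-specific superset model (two extra rates) fits no better and
  # its evidence must fall below the reduced model's
  truth <- discount_params(k = 0.12, theta = 2, family = "hyperbolic_shared")
  losses <- vapply(1:3, function(r) {
    tr <- make_trials(truth, n_trials = 60, seed = 30 + r)
    f_red <- fit_discounting(tr, "hyperbolic_shared", n_restarts = 3, seed = r)
    f_full <- fit_discounting(tr, "hyperbolic_specific", n_restarts = 3, seed = r)
    f_red$log_evidence - f_full$log_evidence
  }, numeric(1))
  expect_gt(mean(losses), 0)
  # a *fully* inert parameter with a standard normal prior integrates out
  # exactly and leaves the Laplace evidence unchanged
  set.seed(11)
  y <- rbinom(200, 1, 0.7)
  ll1 <- function(x) sum(dbinom(y, 1, plogis(x[1]), log = TRUE))
  ll2 <- function(x) sum(dbinom(y, 1, plogis(x[1]), log = TRUE)) # x[2] inert
  f1 <- fit_map(ll1, 0, 1, n_restarts = 3, seed = 3)
  f2 <- fit_map(ll2, c(0, 0), c(1, 1), n_restarts = 3, seed = 3)
  expect_equal(f2$log_evidence, f1$log_evidence, tolerance = 1e-4)
})

test_that("fitting is deterministic given the seed", {
  truth <- discount_params(k_R = 0.1, k_E = 0.2, k_P = 0.1, theta = 2,
                           family = "hyperbolic_specific")
  tr <- make_trials(truth, categories = "reward", n_trials = 40, seed = 4)
  f1 <- fit_discounting(tr, "hyperbolic_specific", n_restarts = 3, seed = 7)
  f2 <- fit_discounting(tr, "hyperbolic_specific", n_restarts = 3, seed = 7)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$log_evidence, f2$log_evidence)
})

test_that("fit_discounting recovers parameters from simulated choices", {
  truth <- discount_params(k_R = 0.05, k_E = 0.25, k_P = 0.1, theta = 2,
                           family = "hyperbolic_specific")
  tr <- make_trials(truth, n_trials = 80, seed = 21)
  fit <- fit_discounting(tr, "hyperbolic_specific", n_restarts = 4, seed = 5)
  expect_equal(fit$params$k_R, 0.05, tolerance = 0.5)
  expect_equal(fit$params$k_E, 0.25, tolerance = 0.5)
  expect_gt(fit$params$k_E, fit$params$k_R)
})

test_that("group comparison sums evidence and reports log Bayes factors", {
  ev <- data.frame(
    participant_id = rep(c("a", "b"), 2),
    family = rep(c("f1", "f2"), each = 2),
    log_evidence = c(-10, -20, -12, -25)
  )
  cmp <- compare_models(ev)
  expect_equal(cmp$best_family, "f1")
  expect_equal(unname(cmp$log_group_bf["f1", "f2"]), 7)
  # two identical families tie at log BF = 0
  ev2 <- ev; ev2$log_evidence <- c(-10, -20, -10, -20)
  expect_equal(unname(compare_models(ev2)$log_group_bf["f1", "f2"]), 0)
  # mismatched participant sets are an error
  ev3 <- ev[-1, ]
  expect_error(compare_models(ev3), "participant sets")
})

test_that("balanced accuracy averages the two per-class accuracies", {
  expect_equal(balanced_accuracy(c(0.9, 0.1, 0.8, 0.2), c(1, 0, 1, 0)), 1)
  # chance predictions score one half under the tie rule
  expect_equal(balanced_accuracy(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  # hand enumeration: each class has one hit and one miss
  expect_equal(balanced_accuracy(c(0.9, 0.2, 0.6, 0.4), c(1, 0, 0, 1)), 0.5)
  # single-class input returns that class's accuracy, flagged
  ba <- balanced_accuracy(c(0.9, 0.8), c(1, 1))
  expect_equal(as.numeric(ba), 1)
  expect_equal(attr(ba, "flags"), "single_class")
  expect_error(balanced_accuracy(numeric(0), numeric(0)), "empty")
})

test_that("calibration bins are equal-count and track observed rates", {
  # n = n_bins: one trial per bin
  cb <- calibration_bins(seq(0.1, 0.8, by = 0.1), rep(c(0, 1), 4), n_bins = 8)
  expect_equal(cb$n, rep(1L, 8))
  expect_true(all(diff(cb$mean_modeled) > 0))
  # identical probabilities collapse to one flagged bin
  cb2 <- calibration_bins(rep(0.4, 20), rbinom(20, 1, 0.4))
  expect_equal(nrow(cb2), 1)
  expect_equal(attr(cb2, "flags"), "degenerate_probabilities")
  # well-calibrated large sample: bin means sit near the identity line
  set.seed(8)
  p <- runif(4000)
  y <- as.integer(runif(4000) < p)
  cb3 <- calibration_bins(p, y, n_bins = 8)
  expect_true(all(abs(cb3$mean_modeled - cb3$mean_observed) <
                    4 * sqrt(0.25 / cb3$n)))
})
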