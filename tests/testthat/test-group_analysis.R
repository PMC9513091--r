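test_that("logistic choice-factor regressions recover generating signs", {
  spec <- population_spec(n_participants = 12, seed = 51)
  pop <- generate_population(spec)
  uv <- unit_values_from_ratings(pop$ratings)
  parts <- pop$participants
  trials <- do.call(rbind, lapply(seq_len(12), function(i) {
    truth <- discount_params(k_R = parts$k_R[i], k_E = parts$k_E[i],
                             k_P = parts$k_P[i], theta = parts$theta[i],
                             family = "hyperbolic_specific")
    make_trials(truth, categories = "reward", n_trials = 60, seed = 60 + i,
                participant_id = parts$id[i],
                unit_values = uv[uv$participant_id == parts$id[i], ])
  }))
  res <- logistic_choice_factors(trials, "intertemporal")
  g <- res$group
  # reward choices: value attracts, delay repels
  expect_gt(g$t[g$factor == "rel_value"], 2)
  expect_lt(g$t[g$factor == "rel_delay"], -2)
  expect_equal(nrow(res$coefficients), 12)
})

test_that("pure-noise choices give null coefficients", {
  uv <- make_unit_values(seed = 52)
  trials <- do.call(rbind, lapply(1:10, function(i) {
    cs <- generate_choice_set(uv, "reward", n_trials = 60, seed = 70 + i,
                              participant_id = sprintf("p%03d", i))
    cs$chose_later <- rbinom(60, 1, 0.5)
    cs
  }))
  set.seed(53)
  res <- logistic_choice_factors(trials, "intertemporal")
  expect_true(all(abs(res$group$t) < 4))
  expect_true(all(res$group$p > 1e-4))
})

test_that("cross-participant regression matches the closed-form OLS oracle", {
  set.seed(54)
  n <- 40
  sm <- data.frame(
    id = sprintf("p%03d", 1:n),
    k_R = rlnorm(n, log(0.06), 0.5), k_E = rlnorm(n, log(0.15), 0.5),
    age = round(rnorm(n, 23, 2.5)), gender = rbinom(n, 1, 0.5)
  )
  sm$procrastination_level <- plogis(0.8 * scale(log(sm$k_E))[, 1] +
                                       rnorm(n, 0, 0.3))
  res <- regress_procrastination(sm, "lab")
  # textbook oracle on the same standardized design
  Z <- scale(cbind(log(sm$k_R), log(sm$k_E), sm$age, sm$gender))
  X <- cbind(1, Z)
  beta_hat <- solve(t(X) %*% X, t(X) %*% sm$procrastination_level)
  expect_equal(res$estimate, as.numeric(beta_hat), tolerance = 1e-8)
  expect_gt(res$t[res$term == "k_E"], 2)
  expect_true(attr(res, "r_squared") > 0 && attr(res, "r_squared") <= 1)
})

test_that("home-outcome regression excludes never-returners", {
  set.seed(55)
  n <- 30
  sm <- data.frame(
    id = sprintf("p%03d", 1:n),
    k_R = rlnorm(n, log(0.06), 0.5), k_E = rlnorm(n, log(0.15), 0.5),
    age = round(rnorm(n, 23, 2.5)), gender = rbinom(n, 1, 0.5),
    form_delay = c(rep(NA, 5), sample(0:30, 25, replace = TRUE))
  )
  res <- regress_procrastination(sm, "home")
  expect_equal(attr(res, "n"), 25)
})

test_that("delays generated by the dynamic model load on the effort rate", {
  spec <- population_spec(n_participants = 120, n_items = 2, seed = 56)
  pop <- generate_population(spec)
  parts <- pop$participants
  delays <- simulate_form_delays(pop, "dynamic", theta = 0.5, seed = 57)
  sm <- cbind(parts, form_delay = delays$form_delay)
  sm$id <- parts$id
  res <- regress_procrastination(sm, "home")
  expect_gt(res$estimate[res$term == "k_E"], 0)
  expect_gt(res$t[res$term == "k_E"], 2)
})

test_that("an independent outcome yields a near-zero R squared", {
  set.seed(58)
  n <- 400
  sm <- data.frame(
    id = as.character(1:n), k_R = rlnorm(n, -2.8, 0.5),
    k_E = rlnorm(n, -1.9, 0.5), age = rnorm(n, 23, 2.5),
    gender = rbinom(n, 1, 0.5),
    procrastination_level = runif(n)
  )
  res <- regress_procrastination(sm, "lab")
  expect_lt(attr(res, "r_squared"), 0.05)
})

test_that("collinear predictors raise an error naming the duplicate", {
  set.seed(59)
  sm <- data.frame(
    id = as.character(1:20), k_R = rlnorm(20, -2.8, 0.5),
    k_E = rlnorm(20, -1.9, 0.5), age = rnorm(20, 23, 2),
    gender = rbinom(20, 1, 0.5), procrastination_level = runif(20)
  )
  sm$k_dup <- sm$k_E
  expect_error(
    regress_procrastination(sm, "lab",
                            predictors = c("k_E", "k_dup", "age", "gender")),
    "collinear"
  )
})

test_that("measure correlations report Pearson r with configured tails", {
  set.seed(60)
  n <- 43
  sm <- data.frame(x = rnorm(n))
  sm$y <- sm$x + rnorm(n, 0, 0.05)
  sm$z <- rnorm(n)
  res <- measure_correlations(sm, c("x", "y", "z"))
  r_xy <- res$r[res$var1 == "x" & res$var2 == "y"]
  expect_gt(r_xy, 0.98)
  expect_equal(res$n, rep(43, 3))
  one <- measure_correlations(sm, c("x", "y"), alternative = "greater")
  expect_lt(one$p, res$p[res$var1 == "x" & res$var2 == "y"])
  expect_error(measure_correlations(sm[1:2, ], c("x", "y")), "fewer than 3")
})

test_that("null correlations have uniform p-values across replications", {
  set.seed(61)
  ps <- replicate(200, {
    d <- data.frame(a = rnorm(20), b = rnorm(20))
    measure_correlations(d, c("a", "b"))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
  expect_lt(mean(abs(replicate(50, {
    d <- data.frame(a = rnorm(43), b = rnorm(43))
    measure_correlations(d, c("a", "b"))$r
  }))), 0.25)
})
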