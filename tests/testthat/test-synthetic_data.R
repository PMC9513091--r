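test_that("population generation is reproducible and sized as specified", {
  spec <- population_spec(n_participants = 43, n_items = 10, seed = 3)
  pop1 <- generate_population(spec)
  pop2 <- generate_population(spec)
  expect_identical(pop1, pop2)
  expect_equal(nrow(pop1$participants), 43)
  expect_equal(nrow(pop1$ratings), 43 * 30)
  expect_true(all(pop1$ratings$q1 > 0 & pop1$ratings$q5 > 0))
  expect_true(all(pop1$participants$form_cost > 0))
})

test_that("zero-variance distributions give degenerate participants", {
  spec <- population_spec(
    n_participants = 1,
    k_R_dist = c(log(0.05), 0), k_E_dist = c(log(0.2), 0),
    k_P_dist = c(log(0.1), 0), theta_dist = c(log(1.5), 0),
    n_items = 2, seed = 1
  )
  p <- generate_population(spec)$participants
  expect_equal(p$k_R, 0.05)
  expect_equal(p$k_E, 0.2)
  expect_equal(p$k_P, 0.1)
  expect_equal(p$theta, 1.5)
})

test_that("population medians track the spec targets", {
  spec <- population_spec(n_participants = 10000, n_items = 1, seed = 12)
  p <- generate_population(spec)$participants
  expect_equal(median(p$k_E), exp(spec$k_E_dist[[1]]), tolerance = 0.05)
  expect_equal(median(p$k_R), exp(spec$k_R_dist[[1]]), tolerance = 0.05)
  expect_gt(median(p$k_E), median(p$k_R))
})

test_that("invalid specs are rejected", {
  expect_error(population_spec(n_participants = 0), "n_participants")
  expect_error(population_spec(deadline = 0), "deadline")
  expect_error(population_spec(k_R_dist = c(0, -1)), "k_R_dist")
})

test_that("choice sets respect the delay set and block structure", {
  uv <- make_unit_values(seed = 41)
  cs <- generate_choice_set(uv, "reward", n_trials = 60, seed = 5)
  expect_equal(nrow(cs), 60)
  delay_set <- c(0, 1, 2, 3, 5, 7, 10, 14, 21, 30)
  expect_true(all(cs$delay_sooner %in% delay_set))
  expect_true(all(cs$delay_later %in% delay_set))
  expect_true(all(cs$delay_sooner < cs$delay_later))
  # no item repeats within a 60-trial block
  expect_equal(length(unique(cs$item_id)), 60)
  # the later option always offers the greater quantity
  expect_true(all(cs$q_later > cs$q_sooner))
  expect_true(all(cs$q_sooner == round(cs$q_sooner) & cs$q_sooner >= 1))
  # empty and degenerate cases
  expect_equal(nrow(generate_choice_set(uv, "reward", n_trials = 0)), 0)
  expect_error(generate_choice_set(uv, "reward", delays = numeric(0)),
               "empty delay set")
  expect_error(generate_choice_set(uv, "reward", a_priori_k = 0), "a_priori_k")
})

test_that("discounted-value differences evenly sample the value space", {
  uv <- make_unit_values(seed = 42)
  k <- 0.1
  cs <- generate_choice_set(uv, "reward", n_trials = 6000, a_priori_k = k,
                            diff_range = c(-4, 4), seed = 6)
  diff <- cs$q_later * cs$unit_value / (1 + k * cs$delay_later) -
    cs$q_sooner * cs$unit_value / (1 + k * cs$delay_sooner)
  counts <- hist(pmin(pmax(diff, -4), 4), breaks = seq(-4, 4, by = 1),
                 plot = FALSE)$counts
  expected <- 6000 / 8
  tol <- 3 * sqrt(6000 * (1 / 8) * (7 / 8))
  expect_lt(max(abs(counts - expected)), tol)
})

test_that("simulated choices follow the softmax probabilities", {
  uv <- make_unit_values(seed = 43)
  # deterministic regime: a hugely steep softmax picks the better option
  steep <- discount_params(k_R = 0.1, k_E = 0.2, k_P = 0.1, theta = 1e4,
                           family = "hyperbolic_specific")
  cs <- generate_choice_set(uv, "reward", n_trials = 50, seed = 7)
  sim <- simulate_choices(cs, steep, seed = 8)
  p <- choice_probability(cs, steep)
  expect_equal(sim$chose_later, as.integer(p > 0.5))
  # chance regime
  flat <- discount_params(k_R = 0.1, k_E = 0.2, k_P = 0.1, theta = 0,
                          family = "hyperbolic_specific")
  big <- generate_choice_set(uv, "reward", n_trials = 4000, seed = 9)
  sim0 <- simulate_choices(big, flat, seed = 10)
  expect_equal(mean(sim0$chose_later), 0.5, tolerance = 0.03)
  # a single repeated offer: empirical frequency matches the model
  one <- cs[rep(1, 10000), ]
  truth <- discount_params(k_R = 0.08, k_E = 0.2, k_P = 0.1, theta = 1,
                           family = "hyperbolic_specific")
  p1 <- choice_probability(one[1, ], truth)
  simf <- simulate_choices(one, truth, seed = 11)
  expect_equal(mean(simf$chose_later), p1,
               tolerance = 4 * sqrt(p1 * (1 - p1) / 10000) / p1)
  # determinism
  expect_identical(simulate_choices(cs, truth, seed = 12),
                   simulate_choices(cs, truth, seed = 12))
})

test_that("form delays follow the chosen completion model", {
  spec <- population_spec(
    n_participants = 30, n_items = 2,
    k_R_dist = c(log(0.3), 0.2), k_E_dist = c(log(0.05), 0.2), seed = 14
  )
  pop <- generate_population(spec)
  # impatient-for-reward population (k_R > k_E): static optimum is now
  sta <- simulate_form_delays(pop, "static_argmax", seed = 15)
  expect_true(all(sta$form_delay == 0))
  # indifferent dynamic agents: delays match the uniform-softmax process
  spec0 <- population_spec(n_participants = 400, n_items = 2, seed = 16)
  pop0 <- generate_population(spec0)
  dyn0 <- simulate_form_delays(pop0, "dynamic", theta = 0, seed = 17)
  expect_true(all(dyn0$form_delay >= 0 & dyn0$form_delay <= 30))
  # theta = 0 expected delay is sum(d * pmf) of the uniform-hazard process
  ref <- dynamic_completion_distribution(
    procrastination_task(50, 30, 0.1, 0.1, theta = 0, deadline = 30)
  )
  se <- sqrt(sum((0:30)^2 * ref$pmf) - ref$expected_delay^2) / sqrt(400)
  expect_lt(abs(mean(dyn0$form_delay) - ref$expected_delay), 4 * se)
  # determinism
  expect_identical(simulate_form_delays(pop, "dynamic", seed = 18),
                   simulate_form_delays(pop, "dynamic", seed = 18))
})
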