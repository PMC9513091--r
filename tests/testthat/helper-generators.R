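# Shared fixture builders. Everything is generated in code at test time.

# A participant's unit-value table with n items per category.
make_unit_values <- function(n_per_cat = 60, seed = 1, participant_id = "p001") {
  cats <- c("reward", "effort", "punishment")
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed(data.frame(
    participant_id = participant_id,
    item_id = unlist(lapply(cats, function(cc) sprintf("%s_%02d", cc, seq_len(n_per_cat)))),
    category = rep(cats, each = n_per_cat),
    value_per_unit = rlnorm(3 * n_per_cat, log(0.4), 0.4),
    stringsAsFactors = FALSE
  ))
}

# Simulated intertemporal trials for one participant under a known truth.
make_trials <- function(truth, categories = c("reward", "effort", "punishment"),
                        n_trials = 60, seed = 1, a_priori_k = 0.1,
                        participant_id = "p001", unit_values = NULL) {
  uv <- unit_values %||% make_unit_values(seed = seed, participant_id = participant_id)
  do.call(rbind, lapply(seq_along(categories), function(j) {
    cs <- generate_choice_set(uv, categories[j], n_trials = n_trials,
                              a_priori_k = a_priori_k, seed = seed + 17 * j,
                              participant_id = participant_id)
    simulate_choices(cs, truth, seed = seed + 1000 + 17 * j)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A multi-participant trial table generated under a given family, drawing
# per-participant parameters from the population spec.
make_family_dataset <- function(gen_family, n_participants = 6, n_trials = 60,
                                seed = 1) {
  spec <- population_spec(n_participants = n_participants, n_items = 60,
                          seed = seed)
  pop <- generate_population(spec)
  uv <- unit_values_from_ratings(pop$ratings)
  parts <- pop$participants
  trials <- lapply(seq_len(n_participants), function(i) {
    truth <- switch(gen_family,
      hyperbolic_specific = discount_params(
        k_R = parts$k_R[i], k_E = parts$k_E[i], k_P = parts$k_P[i],
        theta = parts$theta[i], family = "hyperbolic_specific"),
      hyperbolic_shared = discount_params(
        k = parts$k_R[i], theta = parts$theta[i], family = "hyperbolic_shared"),
      present_bias = discount_params(
        beta = parts$beta[i], theta = parts$theta[i], family = "present_bias"),
      quasi_hyperbolic = discount_params(
        beta = parts$beta[i], delta = parts$delta[i], theta = parts$theta[i],
        family = "quasi_hyperbolic"))
    make_trials(truth, n_trials = n_trials, seed = seed + 37 * i,
                participant_id = parts$id[i],
                unit_values = uv[uv$participant_id == parts$id[i], ])
  })
  list(trials = do.call(rbind, trials), participants = parts, spec = spec)
}

# A random admissible home task with rates and values in the reference
# simulation ranges.
random_task <- function(k_R = runif(1, 0, 0.5), k_E = runif(1, 0, 0.5),
                        R = runif(1, 40, 60), E = runif(1, 20, 40),
                        theta = 0.5, deadline = 30) {
  procrastination_task(R, E, k_R, k_E, theta, deadline)
}
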