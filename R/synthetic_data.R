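# Synthetic participants, ratings, choice sets, choices and form-return
# delays with the statistical structure the downstream analyses assume.

DEFAULT_DELAY_SET <- c(0, 1, 2, 3, 5, 7, 10, 14, 21, 30)

SUBCATEGORIES <- list(
  reward = c("food", "goods"),
  effort = c("cognitive", "motor"),
  punishment = c("bodily", "abstract")
)

#' Specification of a synthetic participant population
#'
#' Discount rates are drawn log-normally (rates are positive and
#' right-skewed); each `*_dist` is `c(meanlog, sdlog)`, so the population
#' median rate is `exp(meanlog)`. Defaults put the median effort rate
#' above the median reward rate (steeper discounting of effort than of
#' reward, the pattern that produces procrastination), with the
#' punishment rate in between. Reward value and effort cost of the home
#' form-filling task are drawn uniformly from `reward_value_range` and
#' `effort_cost_range`.
#'
#' @param n_participants number of participants, `>= 1`.
#' @param k_R_dist,k_E_dist,k_P_dist `c(meanlog, sdlog)` of the log-normal
#'   discount-rate distributions (per day); `sdlog = 0` gives a
#'   degenerate distribution at `exp(meanlog)`.
#' @param theta_dist `c(meanlog, sdlog)` of the inverse temperature.
#' @param beta_range,delta_range uniform ranges for the present-bias and
#'   exponential factors (used only when generating under those
#'   families).
#' @param reward_value_range,effort_cost_range uniform ranges (euros or
#'   arbitrary units) for the home task's compensation and subjective
#'   form-filling cost.
#' @param unit_value_dist `c(meanlog, sdlog)` of latent per-unit item
#'   values (euros per unit).
#' @param rating_noise SD of the multiplicative log-normal jitter applied
#'   to the two monetary-equivalence ratings of each item.
#' @param n_items items per category in the rating/choice catalogs.
#' @param deadline days allowed for the home task, `>= 1`.
#' @param decision_rate decisions per day in the home-task simulation
#'   (default 1, one decision each day).
#' @param seed integer seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_participants = 43,
                            k_R_dist = c(meanlog = log(0.06), sdlog = 0.5),
                            k_E_dist = c(meanlog = log(0.15), sdlog = 0.5),
                            k_P_dist = c(meanlog = log(0.10), sdlog = 0.5),
                            theta_dist = c(meanlog = log(2), sdlog = 0.3),
                            beta_range = c(0.5, 0.9),
                            delta_range = c(0.9, 0.99),
                            reward_value_range = c(40, 60),
                            effort_cost_range = c(20, 40),
                            unit_value_dist = c(meanlog = log(0.4), sdlog = 0.4),
                            rating_noise = 0.1,
                            n_items = 60,
                            deadline = 30,
                            decision_rate = 1,
                            seed = 1) {
  if (n_participants < 1) stop_config("`n_participants` must be >= 1")
  if (deadline < 1) stop_config("`deadline` must be >= 1")
  for (nm in c("k_R_dist", "k_E_dist", "k_P_dist", "theta_dist", "unit_value_dist")) {
    d <- get(nm)
    if (length(d) != 2 || !all(is.finite(d)) || d[2] < 0) {
      stop_config("`", nm, "` must be c(meanlog, sdlog) with sdlog >= 0")
    }
  }
  if (rating_noise < 0) stop_config("`rating_noise` must be >= 0")
  structure(as.list(environment()), class = "population_spec")
}

#' Generate a synthetic participant population
#'
#' Draws per-participant discount parameters from the population spec,
#' latent per-unit item values for a catalog of reward, effort and
#' punishment items, and the two monetary-equivalence ratings per item
#' (the latent value inverted, with multiplicative log-normal jitter).
#' Age and gender are nuisance covariates, uncorrelated with the
#' parameters. Deterministic given `spec$seed`.
#'
#' @param spec a [population_spec()].
#' @return list of class `synthetic_population`: `participants` (one row
#'   per participant: true parameters, home-task reward/cost, covariates),
#'   `ratings` (rating-task table) and `spec`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_participants
  with_seed(spec$seed, {
    participants <- data.frame(
      id = sprintf("p%03d", seq_len(n)),
      k_R = stats::rlnorm(n, spec$k_R_dist[1], spec$k_R_dist[2]),
      k_E = stats::rlnorm(n, spec$k_E_dist[1], spec$k_E_dist[2]),
      k_P = stats::rlnorm(n, spec$k_P_dist[1], spec$k_P_dist[2]),
      theta = stats::rlnorm(n, spec$theta_dist[1], spec$theta_dist[2]),
      beta = stats::runif(n, spec$beta_range[1], spec$beta_range[2]),
      delta = stats::runif(n, spec$delta_range[1], spec$delta_range[2]),
      compensation = stats::runif(n, spec$reward_value_range[1],
                                  spec$reward_value_range[2]),
      form_cost = stats::runif(n, spec$effort_cost_range[1],
                               spec$effort_cost_range[2]),
      age = pmin(pmax(round(stats::rnorm(n, 23, 2.5)), 18), 40),
      gender = stats::rbinom(n, 1, 0.6),
      questionnaire_score = pmin(pmax(round(stats::rnorm(n, 3, 0.8), 2), 1), 5),
      stringsAsFactors = FALSE
    )
    catalog <- do.call(rbind, lapply(CATEGORIES, function(cat) {
      data.frame(
        item_id = sprintf("%s_%02d", cat, seq_len(spec$n_items)),
        category = cat,
        subcategory = rep_len(SUBCATEGORIES[[cat]], spec$n_items),
        stringsAsFactors = FALSE
      )
    }))
    ratings <- do.call(rbind, lapply(seq_len(n), function(i) {
      v <- stats::rlnorm(nrow(catalog), spec$unit_value_dist[1],
                         spec$unit_value_dist[2])
      data.frame(
        participant_id = participants$id[i],
        item_id = catalog$item_id,
        category = catalog$category,
        subcategory = catalog$subcategory,
        q1 = (1 / v) * stats::rlnorm(nrow(catalog), 0, spec$rating_noise),
        q5 = (5 / v) * stats::rlnorm(nrow(catalog), 0, spec$rating_noise),
        stringsAsFactors = FALSE
      )
    }))
    structure(list(participants = participants, ratings = ratings, spec = spec),
              class = "synthetic_population")
  })
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("<synthetic_population>", nrow(x$participants), "participants,",
      nrow(x$ratings), "item ratings\n")
  invisible(x)
}

#' Generate an intertemporal choice set for one participant
#'
#' Builds trials pairing a sooner/lower with a later/greater quantity of
#' the same item. Delays are drawn from the standard ten-delay set;
#' items are drawn without repetition within blocks. Quantities are
#' adjusted from the item's per-unit value, the delays and an a-priori
#' discount rate so that the discounted-value differences between the
#' two options cover a uniform grid over `diff_range` (evenly sampling
#' the value space): the target difference is inverted for the later
#' quantity under the a-priori rate and rounded to the nearest positive
#' integer, resampling the delay pair when the later quantity would not
#' exceed the sooner one.
#'
#' @param unit_values one participant's unit-value table
#'   (`item_id`, `category`, `value_per_unit`).
#' @param category `"reward"`, `"effort"` or `"punishment"`.
#' @param n_trials number of trials.
#' @param delays admissible delay set (days).
#' @param a_priori_k a-priori discount rate used to calibrate quantities.
#' @param value_range uniform range (euros) of the sooner option's
#'   undiscounted value.
#' @param diff_range range (euros) of target discounted-value
#'   differences (later minus sooner).
#' @param seed integer seed.
#' @param participant_id id copied into the output.
#' @return data frame of trials (no picks): `participant_id`, `trial`,
#'   `item_id`, `category`, `unit_value`, `q_sooner`, `delay_sooner`,
#'   `q_later`, `delay_later`.
#' @export
generate_choice_set <- function(unit_values, category, n_trials = 60,
                                delays = DEFAULT_DELAY_SET,
                                a_priori_k = 0.1,
                                value_range = c(2, 8),
                                diff_range = c(-4, 4),
                                seed = 1,
                                participant_id = "p001") {
  if (length(delays) == 0) stop_config("empty delay set")
  if (a_priori_k <= 0) stop_config("`a_priori_k` must be > 0")
  items <- unit_values[unit_values$category == category, , drop = FALSE]
  if (nrow(items) == 0) stop_config("no items of category '", category, "'")
  if (n_trials == 0) {
    return(data.frame(participant_id = character(0), trial = integer(0),
                      item_id = character(0), category = character(0),
                      unit_value = numeric(0), q_sooner = numeric(0),
                      delay_sooner = numeric(0), q_later = numeric(0),
                      delay_later = numeric(0), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    # items without repetition within blocks of the catalog size
    idx <- unlist(lapply(seq_len(ceiling(n_trials / nrow(items))),
                         function(b) sample(nrow(items))))[seq_len(n_trials)]
    # uniform grid of target discounted-value differences, shuffled
    target <- sample(seq(diff_range[1], diff_range[2], length.out = n_trials))
    base <- stats::runif(n_trials, value_range[1], value_range[2])
    # a strongly negative target difference is only reachable when the
    # sooner option is valuable enough; raise the base value if needed
    base <- pmax(base, -1.6 * target)
    out <- lapply(seq_len(n_trials), function(i) {
      r <- items$value_per_unit[idx[i]]
      q_s <- q_l <- d_s <- d_l <- NA_real_
      for (try in 1:50) {
        dd <- if (length(delays) >= 2) sort(sample(delays, 2)) else c(delays, delays)
        if (dd[1] == dd[2]) next
        q_s <- max(1, round(base[i] / r))
        v_s <- q_s * r / (1 + a_priori_k * dd[1])
        v_l_target <- v_s + target[i]
        if (v_l_target < 0.2) next
        q_l_raw <- v_l_target * (1 + a_priori_k * dd[2]) / r
        if (q_l_raw < q_s + 0.5) next
        q_l <- round(q_l_raw); d_s <- dd[1]; d_l <- dd[2]
        break
      }
      if (is.na(q_l)) {
        # fallback: widest delay gap, clamped later quantity
        d_s <- min(delays); d_l <- max(delays)
        q_s <- max(1, round(base[i] / r))
        v_s <- q_s * r / (1 + a_priori_k * d_s)
        q_l <- max(q_s + 1, round(max(0.2, v_s + target[i]) *
                                    (1 + a_priori_k * d_l) / r))
      }
      data.frame(participant_id = participant_id, trial = i,
                 item_id = items$item_id[idx[i]], category = category,
                 unit_value = r, q_sooner = q_s, delay_sooner = d_s,
                 q_later = q_l, delay_later = d_l, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate choices on an intertemporal choice set
#'
#' Draws each pick as a Bernoulli with the softmax choice probability
#' under the supplied parameters.
#'
#' @param trials trials from [generate_choice_set()].
#' @param params a [discount_params()] object (the generating truth).
#' @param seed integer seed.
#' @return `trials` with a `chose_later` column added.
#' @export
simulate_choices <- function(trials, params, seed = 1) {
  p <- choice_probability(trials, params)
  trials$chose_later <- with_seed(seed, as.integer(stats::runif(nrow(trials)) < p))
  trials
}

#' Generate a now/tomorrow choice set for one participant
#'
#' Each offer combines a reward item and an effort item; quantities are
#' adjusted from the participant's unit values so that reward values and
#' effort costs are drawn from the same uniform distribution.
#'
#' @param unit_values one participant's unit-value table.
#' @param n_trials number of offers.
#' @param value_range common uniform range (euros) of reward value and
#'   effort cost on offer.
#' @param block_size offers per block (items not repeated within blocks).
#' @param seed integer seed.
#' @param participant_id id copied into the output.
#' @return data frame `participant_id`, `trial`, `reward_item`,
#'   `effort_item`, `N_R`, `R_i`, `N_E`, `E_j`.
#' @export
generate_now_tomorrow_set <- function(unit_values, n_trials = 150,
                                      value_range = c(1, 10),
                                      block_size = 50, seed = 1,
                                      participant_id = "p001") {
  rew <- unit_values[unit_values$category == "reward", , drop = FALSE]
  eff <- unit_values[unit_values$category == "effort", , drop = FALSE]
  if (nrow(rew) == 0 || nrow(eff) == 0) {
    stop_config("need both reward and effort items")
  }
  with_seed(seed, {
    pick_items <- function(tbl) {
      per_block <- min(block_size, nrow(tbl))
      unlist(lapply(seq_len(ceiling(n_trials / per_block)),
                    function(b) sample(nrow(tbl), per_block)))[seq_len(n_trials)]
    }
    ri <- pick_items(rew); ei <- pick_items(eff)
    target_R <- stats::runif(n_trials, value_range[1], value_range[2])
    target_E <- stats::runif(n_trials, value_range[1], value_range[2])
    N_R <- pmax(1, round(target_R / rew$value_per_unit[ri]))
    N_E <- pmax(1, round(target_E / eff$value_per_unit[ei]))
    data.frame(participant_id = participant_id, trial = seq_len(n_trials),
               reward_item = rew$item_id[ri], effort_item = eff$item_id[ei],
               N_R = N_R, R_i = rew$value_per_unit[ri],
               N_E = N_E, E_j = eff$value_per_unit[ei],
               stringsAsFactors = FALSE)
  })
}

#' Simulate now/tomorrow choices
#'
#' @param trials offers from [generate_now_tomorrow_set()].
#' @param k_R,k_E discount rates of the simulated participant.
#' @param theta inverse temperature.
#' @param seed integer seed.
#' @return `trials` with a `chose_tomorrow` column added.
#' @export
simulate_now_tomorrow_choices <- function(trials, k_R, k_E, theta, seed = 1) {
  p <- now_tomorrow_prob(trials, k_R, k_E, theta)
  trials$chose_tomorrow <- with_seed(seed, as.integer(stats::runif(nrow(trials)) < p))
  trials
}

#' Simulate form-return delays for a population
#'
#' Builds each participant's home task from their compensation, rated
#' form-filling cost and true discount rates, then draws the return
#' delay under the chosen completion model: `"dynamic"` samples the
#' iterated-decision process, `"static_softmax"` samples the one-shot
#' softmax readout and `"static_argmax"` is the deterministic optimum.
#' All delays lie in `[0, deadline]`.
#'
#' @param population a `synthetic_population` (or its `participants`
#'   data frame plus `deadline`).
#' @param model completion model.
#' @param theta inverse temperature of the completion softmax.
#' @param normalize value normalization. The default `"none"` applies the
#'   softmax on the common raw value scale, the regime of the reference
#'   grid simulations (reward 40-60, cost 20-40 a.u., `theta = 0.5`);
#'   per-participant normalization exists to absorb differences in value
#'   *units* when fitting observed data, which synthetic populations on a
#'   shared scale do not have.
#' @param seed integer seed.
#' @param deadline days; defaults to the population spec's deadline.
#' @return data frame `id`, `form_delay` (days).
#' @export
simulate_form_delays <- function(population,
                                 model = c("dynamic", "static_softmax", "static_argmax"),
                                 theta = 0.5,
                                 normalize = c("none", "max_abs", "zscore"),
                                 seed = 1, deadline = NULL) {
  model <- match.arg(model)
  normalize <- match.arg(normalize)
  if (inherits(population, "synthetic_population")) {
    parts <- population$participants
    deadline <- deadline %||% population$spec$deadline
  } else {
    parts <- population
    deadline <- deadline %||% 30
  }
  with_seed(seed, {
    delay <- vapply(seq_len(nrow(parts)), function(i) {
      task <- procrastination_task(parts$compensation[i], parts$form_cost[i],
                                   parts$k_R[i], parts$k_E[i], theta, deadline)
      switch(model,
        static_argmax = as.numeric(static_optimal_delay(task, "argmax")),
        static_softmax = {
          dist <- static_optimal_delay(task, "softmax", normalize = normalize)
          sample(dist$day, 1, prob = dist$pmf)
        },
        dynamic = {
          dist <- dynamic_completion_distribution(task, normalize = normalize)
          sample(dist$day, 1, prob = dist$pmf)
        }
      )
    }, numeric(1))
    data.frame(id = parts$id, form_delay = delay, stringsAsFactors = FALSE)
  })
}
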