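# Static and dynamic models of recurrent task-completion delay.

#' A recurrent task to be completed before a deadline
#'
#' The "fill-in-the-forms" problem: a reward `R` (financial compensation,
#' paid on completion) and an effort cost `E` (subjective cost of doing
#' the task), both discounted hyperbolically with the completion delay,
#' and a hard deadline `D` days away after which the reward is lost.
#'
#' @param R reward value (euros or arbitrary units), `> 0`.
#' @param E effort cost (same units), `> 0`.
#' @param k_R,k_E hyperbolic discount rates per day (must satisfy the
#'   denominator guard over `[0, deadline]`).
#' @param theta inverse temperature of the completion softmax.
#' @param deadline integer number of days, `>= 1`.
#' @return object of class `procrastination_task`.
#' @export
procrastination_task <- function(R, E, k_R, k_E, theta = 0.5, deadline = 30) {
  if (deadline < 1 || deadline != round(deadline)) {
    stop("`deadline` must be an integer >= 1", call. = FALSE)
  }
  if (R <= 0 || E <= 0) stop("`R` and `E` must be positive", call. = FALSE)
  if (theta < 0) stop("`theta` must be >= 0", call. = FALSE)
  d <- 0:deadline
  if (any(1 + k_R * d <= 0) || any(1 + k_E * d <= 0)) {
    stop("discount denominators must stay positive over [0, deadline]", call. = FALSE)
  }
  structure(list(R = R, E = E, k_R = k_R, k_E = k_E, theta = theta,
                 deadline = as.integer(deadline)),
            class = "procrastination_task")
}

#' Net value of completing a task on each day
#'
#' `V_d = R / (1 + k_R d) - E / (1 + k_E d)` for `d = 0..deadline`.
#' When `k_R = k_E = k` this is `(R - E) / (1 + k d)`: monotone in `d`
#' with the sign of `R - E`.
#'
#' @param task a [procrastination_task()].
#' @return numeric vector of length `deadline + 1` (days 0..deadline).
#' @export
net_value_curve <- function(task) {
  d <- 0:task$deadline
  task$R / (1 + task$k_R * d) - task$E / (1 + task$k_E * d)
}

# Per-task value normalization, absorbing interindividual differences in
# value range before the softmax. Default: divide by the maximum absolute
# net value over the horizon; "zscore" is the documented alternative.
normalize_net_values <- function(v, normalize = c("max_abs", "zscore", "none")) {
  normalize <- match.arg(normalize)
  switch(normalize,
    max_abs = {
      m <- max(abs(v))
      if (m > 0) v / m else v
    },
    zscore = {
      s <- stats::sd(v)
      if (s > 0) (v - mean(v)) / s else v - mean(v)
    },
    none = v
  )
}

#' Optimal completion day under the static model
#'
#' The static model pre-commits: the completion day is chosen once, at
#' day 0, as the day maximizing the net-value curve (`mode = "argmax"`,
#' ties broken toward the earliest day). The stochastic readout
#' (`mode = "softmax"`) instead returns a completion-day distribution by
#' passing all net values through a softmax, which is also the static
#' model's likelihood (the argmax readout is degenerate and cannot score
#' off-optimum observations).
#'
#' @param task a [procrastination_task()].
#' @param mode `"argmax"` (a single day) or `"softmax"` (a distribution).
#' @param normalize value normalization applied before the softmax.
#' @return `argmax`: integer day. `softmax`: a `completion_distribution`
#'   (see [dynamic_completion_distribution()]).
#' @export
static_optimal_delay <- function(task, mode = c("argmax", "softmax"),
                                 normalize = c("max_abs", "zscore", "none")) {
  mode <- match.arg(mode)
  v <- net_value_curve(task)
  if (mode == "argmax") return(which.max(v) - 1L)
  vn <- task$theta * normalize_net_values(v, normalize)
  pmf <- exp(vn - max(vn))
  pmf <- pmf / sum(pmf)
  new_completion_distribution(pmf)
}

#' Daily completion probability under the dynamic model
#'
#' On day `d`, given the task is still pending, the agent compares the
#' net value of doing it now against doing it on any of the remaining
#' days before the deadline (the value of "in t days" is time-invariant:
#' it is re-discounted from the current day). The completion hazard is
#' the softmax probability of the "now" option over the shrinking
#' horizon; at `d = deadline` only "now" remains and the probability is
#' exactly 1. With `theta = 0` it is `1 / (D - d + 1)`.
#'
#' @param task a [procrastination_task()].
#' @param d day index, `0 <= d <= deadline` (vectorized).
#' @param normalize value normalization (see [static_optimal_delay()]).
#' @return probability of completing on day `d` given not yet completed.
#' @export
dynamic_daily_prob <- function(task, d, normalize = c("max_abs", "zscore", "none")) {
  if (any(d < 0 | d > task$deadline)) {
    stop("`d` must lie in [0, deadline]", call. = FALSE)
  }
  dynamic_hazards(task, normalize)[d + 1L]
}

# Completion hazards for d = 0..D. The softmax over the remaining horizon
# uses cumulative sums of exp(theta * v), shifted by the max for stability.
dynamic_hazards <- function(task, normalize = c("max_abs", "zscore", "none")) {
  v <- task$theta * normalize_net_values(net_value_curve(task), normalize)
  w <- exp(v - max(v))
  csum <- cumsum(w)                      # sum over t = 0..h
  D <- task$deadline
  # day d has horizon h = D - d, so the denominator is csum[D - d + 1]
  w[1] / csum[(D:0) + 1L]
}

new_completion_distribution <- function(pmf) {
  day <- seq_along(pmf) - 1L
  cdf <- cumsum(pmf)
  structure(list(day = day, pmf = pmf, cdf = cdf,
                 expected_delay = sum(day * pmf)),
            class = "completion_distribution")
}

#' Completion-time distribution under the dynamic model
#'
#' Procrastination as iterated daily decisions: the probability of
#' having completed the task by day `d` is one minus the product of the
#' daily postponement probabilities up to `d`. The deadline-day hazard
#' is 1 by construction, so the CDF reaches exactly 1 at the deadline;
#' the expected delay `sum(d * pmf)` is the model's predicted
#' procrastination duration.
#'
#' @param task a [procrastination_task()].
#' @param normalize value normalization (see [static_optimal_delay()]).
#' @return object of class `completion_distribution` with elements
#'   `day`, `daily_prob` (hazards), `pmf`, `cdf`, `expected_delay`.
#' @export
dynamic_completion_distribution <- function(task,
                                            normalize = c("max_abs", "zscore", "none")) {
  h <- dynamic_hazards(task, normalize)
  surv <- cumprod(1 - h)                 # P(still pending after day d)
  pmf <- h * c(1, utils::head(surv, -1)) # reach day d pending, act on day d
  out <- new_completion_distribution(pmf)
  out$daily_prob <- h
  out
}

#' @export
print.completion_distribution <- function(x, ...) {
  cat("<completion_distribution> days 0..", max(x$day),
      sprintf("; expected delay %.3f days\n", x$expected_delay))
  invisible(x)
}

#' Log-likelihood of an observed completion delay
#'
#' Log of the model's completion-time pmf at the observed day. The
#' discount rates in the task are fixed inputs (rigidly incorporated from
#' the intertemporal-choice fits); the static model is scored through its
#' softmax readout, never through the degenerate argmax.
#'
#' @param task a [procrastination_task()].
#' @param observed_delay observed completion day, in `[0, deadline]`
#'   (participants who never complete are excluded upstream).
#' @param model `"dynamic"` or `"static_softmax"`.
#' @param normalize value normalization.
#' @return scalar log-likelihood.
#' @export
delay_loglik <- function(task, observed_delay,
                         model = c("dynamic", "static_softmax"),
                         normalize = c("max_abs", "zscore", "none")) {
  model <- match.arg(model)
  if (length(observed_delay) != 1L || observed_delay < 0 ||
      observed_delay > task$deadline || observed_delay != round(observed_delay)) {
    stop("`observed_delay` must be an integer day in [0, deadline]", call. = FALSE)
  }
  dist <- switch(model,
    dynamic = dynamic_completion_distribution(task, normalize),
    static_softmax = static_optimal_delay(task, mode = "softmax",
                                          normalize = normalize)
  )
  log(clip_prob(dist$pmf[observed_delay + 1L]))
}

#' Fit a completion-delay model to one observed delay
#'
#' MAP fit of the inverse temperature (log scale, standard normal prior)
#' of the dynamic or static-softmax completion model, with the task's
#' reward, cost and discount rates held fixed. Used for group-level
#' comparison of the two accounts of procrastination.
#'
#' @param task a [procrastination_task()] (its `theta` is ignored).
#' @param observed_delay observed completion day.
#' @param model `"dynamic"` or `"static_softmax"`.
#' @param normalize value normalization.
#' @param n_restarts,seed passed to [fit_map()].
#' @return a `map_fit` with a `theta` element.
#' @export
fit_delay_model <- function(task, observed_delay,
                            model = c("dynamic", "static_softmax"),
                            normalize = c("max_abs", "zscore", "none"),
                            n_restarts = 5, seed = 1) {
  model <- match.arg(model)
  normalize <- match.arg(normalize)
  ll <- function(x) {
    t2 <- task
    t2$theta <- exp(x[1])
    delay_loglik(t2, observed_delay, model = model, normalize = normalize)
  }
  fit <- fit_map(ll, 0, 1, n_restarts = n_restarts, seed = seed,
                 par_names = "log_theta")
  fit$theta <- exp(fit$par[[1]])
  fit
}

#' Mean procrastination duration over the discount-rate plane
#'
#' Monte-Carlo simulation of expected completion delay, sampling tasks
#' uniformly over ranges of `k_R`, `k_E`, reward value and effort cost,
#' then averaging the expected delay within cells of the
#' `(k_R, k_E)` plane (marginalizing reward and cost).
#'
#' @param n_samples number of sampled tasks.
#' @param k_R_range,k_E_range,R_range,E_range sampling ranges.
#' @param theta inverse temperature.
#' @param deadline days.
#' @param model `"dynamic"` or `"static"` (argmax delay).
#' @param n_bins grid resolution per rate axis.
#' @param normalize value normalization for the dynamic model; the
#'   default `"none"` keeps the common arbitrary-unit scale of the
#'   sampled tasks (see [simulate_form_delays()]).
#' @param seed integer seed.
#' @return data frame `k_R_mid`, `k_E_mid`, `n`, `mean_duration` (one row
#'   per non-empty cell).
#' @export
simulate_duration_grid <- function(n_samples = 10000,
                                   k_R_range = c(0, 0.5), k_E_range = c(0, 0.5),
                                   R_range = c(40, 60), E_range = c(20, 40),
                                   theta = 0.5, deadline = 30,
                                   model = c("dynamic", "static"),
                                   n_bins = 10,
                                   normalize = c("none", "max_abs", "zscore"),
                                   seed = 1) {
  model <- match.arg(model)
  normalize <- match.arg(normalize)
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  draws <- with_seed(seed, data.frame(
    k_R = stats::runif(n_samples, k_R_range[1], k_R_range[2]),
    k_E = stats::runif(n_samples, k_E_range[1], k_E_range[2]),
    R = stats::runif(n_samples, R_range[1], R_range[2]),
    E = stats::runif(n_samples, E_range[1], E_range[2])
  ))
  dur <- vapply(seq_len(n_samples), function(i) {
    task <- procrastination_task(draws$R[i], draws$E[i], draws$k_R[i],
                                 draws$k_E[i], theta, deadline)
    if (model == "dynamic") {
      dynamic_completion_distribution(task, normalize)$expected_delay
    } else {
      as.numeric(static_optimal_delay(task, mode = "argmax"))
    }
  }, numeric(1))
  brk_R <- seq(k_R_range[1], k_R_range[2], length.out = n_bins + 1)
  brk_E <- seq(k_E_range[1], k_E_range[2], length.out = n_bins + 1)
  bin_R <- cut(draws$k_R, brk_R, include.lowest = TRUE, labels = FALSE)
  bin_E <- cut(draws$k_E, brk_E, include.lowest = TRUE, labels = FALSE)
  agg <- stats::aggregate(dur, by = list(bin_R = bin_R, bin_E = bin_E),
                          FUN = function(x) c(n = length(x), mean = mean(x)))
  data.frame(
    k_R_mid = (brk_R[agg$bin_R] + brk_R[agg$bin_R + 1]) / 2,
    k_E_mid = (brk_E[agg$bin_E] + brk_E[agg$bin_E + 1]) / 2,
    n = agg$x[, "n"],
    mean_duration = agg$x[, "mean"]
  )
}

#' Simulate agents completing a task under the dynamic model
#'
#' Process-level simulation: each agent flips the daily completion coin
#' with the dynamic hazard until it completes (the deadline-day hazard
#' is 1, so every agent completes by the deadline). Used as a
#' Monte-Carlo cross-check of the analytic completion distribution and
#' to generate synthetic form-return delays.
#'
#' @param task a [procrastination_task()].
#' @param n number of agents.
#' @param normalize value normalization.
#' @param seed integer seed.
#' @return integer vector of `n` completion days.
#' @export
simulate_completion <- function(task, n,
                                normalize = c("max_abs", "zscore", "none"),
                                seed = 1) {
  h <- dynamic_hazards(task, normalize)
  with_seed(seed, {
    day <- rep(NA_integer_, n)
    pending <- rep(TRUE, n)
    for (d in 0:task$deadline) {
      act <- pending & (stats::runif(n) < h[d + 1L])
      day[act] <- d
      pending <- pending & !act
      if (!any(pending)) break
    }
    day
  })
}
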