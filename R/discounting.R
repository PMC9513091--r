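# Discounting kernels and the softmax choice rule.

DISCOUNT_FAMILIES <- c(
  "hyperbolic_specific", "hyperbolic_shared",
  "present_bias", "quasi_hyperbolic"
)

CATEGORIES <- c("reward", "effort", "punishment")

#' Discounting model parameters
#'
#' Bundles per-participant parameters with the model-family tag that says
#' which are active:
#'
#' * `hyperbolic_specific`: one hyperbolic rate per outcome category
#'   (`k_R`, `k_E`, `k_P`), plus inverse temperature `theta`.
#' * `hyperbolic_shared`: a single hyperbolic rate `k` shared across
#'   categories, plus `theta`.
#' * `present_bias`: multiplicative penalty `beta` on all non-immediate
#'   outcomes, plus `theta`.
#' * `quasi_hyperbolic`: present bias `beta` combined with a constant
#'   per-day exponential factor `delta`, plus `theta`.
#'
#' Rates are per day; `theta` is per euro. Negative rates are admitted
#' down to the hyperbolic guard `k > -1/max_delay` (so denominators stay
#' positive over the admissible delay range).
#'
#' @param k_R,k_E,k_P hyperbolic discount rates (per day) for reward,
#'   effort, punishment. For `hyperbolic_shared` supply `k` instead.
#' @param k shared rate, `hyperbolic_shared` only.
#' @param theta inverse temperature, `>= 0`.
#' @param beta present-bias factor in `[0, 1]`.
#' @param delta daily exponential factor in `[0, 1]`.
#' @param family model family tag.
#' @param max_delay largest delay (days) the parameters must be valid for.
#' @return an object of class `discount_params`.
#' @export
discount_params <- function(k_R = NA_real_, k_E = NA_real_, k_P = NA_real_,
                            k = NA_real_, theta = 1,
                            beta = NA_real_, delta = NA_real_,
                            family = DISCOUNT_FAMILIES, max_delay = 30) {
  family <- match.arg(family, DISCOUNT_FAMILIES)
  if (!is.finite(theta) || theta < 0) stop("`theta` must be >= 0", call. = FALSE)
  guard <- -1 / max_delay
  check_k <- function(x, nm) {
    if (is.finite(x) && x <= guard) {
      stop(sprintf("`%s` = %.3f violates the hyperbolic guard k > %.4f", nm, x, guard),
           call. = FALSE)
    }
  }
  if (family == "hyperbolic_shared") {
    if (!is.finite(k)) stop("`k` is required for family 'hyperbolic_shared'", call. = FALSE)
    check_k(k, "k")
    k_R <- k_E <- k_P <- k
  }
  if (family == "hyperbolic_specific") {
    check_k(k_R, "k_R"); check_k(k_E, "k_E"); check_k(k_P, "k_P")
  }
  if (family %in% c("present_bias", "quasi_hyperbolic")) {
    if (!is.finite(beta) || beta < 0 || beta > 1) {
      stop("`beta` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (family == "quasi_hyperbolic") {
    if (!is.finite(delta) || delta < 0 || delta > 1) {
      stop("`delta` must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(k_R = k_R, k_E = k_E, k_P = k_P, theta = theta,
         beta = beta, delta = delta, family = family, max_delay = max_delay),
    class = "discount_params"
  )
}

#' @export
print.discount_params <- function(x, ...) {
  cat("<discount_params> family:", x$family, "\n")
  active <- switch(x$family,
    hyperbolic_specific = c("k_R", "k_E", "k_P", "theta"),
    hyperbolic_shared = c("k_R", "theta"),
    present_bias = c("beta", "theta"),
    quasi_hyperbolic = c("beta", "delta", "theta")
  )
  for (nm in active) cat(sprintf("  %-6s %.4g\n", nm, x[[nm]]))
  invisible(x)
}

#' Hyperbolic discounting
#'
#' `V = A / (1 + k D)` for an undiscounted amount `A` (euros) delivered
#' after delay `D` (days). Strictly decreasing in `D` for `k > 0`;
#' identity at `D = 0` or `k = 0`.
#'
#' @param amount undiscounted amount in euros (quantity times unit value).
#' @param k hyperbolic discount rate per day.
#' @param delay delay in days, `>= 0`.
#' @return discounted value in euros.
#' @export
hyperbolic_value <- function(amount, k, delay) {
  if (any(delay < 0)) stop("`delay` must be nonnegative", call. = FALSE)
  den <- 1 + k * delay
  if (any(den <= 0)) {
    stop("hyperbolic denominator 1 + k*D must be positive", call. = FALSE)
  }
  amount / den
}

#' Present-bias discounting
#'
#' Immediate outcomes keep their full amount; every delayed outcome is
#' scaled by `beta`, regardless of how long the delay is:
#' `V = A` if `D = 0`, else `beta * A`.
#'
#' @inheritParams hyperbolic_value
#' @param beta present-bias factor in `[0, 1]`.
#' @export
present_bias_value <- function(amount, beta, delay) {
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 1)) {
    stop("`beta` must lie in [0, 1]", call. = FALSE)
  }
  if (any(delay < 0)) stop("`delay` must be nonnegative", call. = FALSE)
  ifelse(delay == 0, amount, beta * amount)
}

#' Quasi-hyperbolic (beta-delta) discounting
#'
#' `V = A` if `D = 0`, else `beta * delta^D * A`: present bias combined
#' with constant per-day exponential discounting. With `delta = 1` it
#' reduces exactly to the present-bias model.
#'
#' @inheritParams present_bias_value
#' @param delta daily exponential factor in `[0, 1]`.
#' @export
quasi_hyperbolic_value <- function(amount, beta, delta, delay) {
  if (any(!is.finite(delta)) || any(delta < 0) || any(delta > 1)) {
    stop("`delta` must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 1)) {
    stop("`beta` must lie in [0, 1]", call. = FALSE)
  }
  if (any(delay < 0)) stop("`delay` must be nonnegative", call. = FALSE)
  ifelse(delay == 0, amount, beta * delta^delay * amount)
}

#' Softmax choice probability
#'
#' `P(A) = 1 / (1 + exp(-theta (V_A - V_B)))`. Overflow-safe: for large
#' `|theta (V_A - V_B)|` it returns the 0/1 limits rather than NaN.
#' Translation-invariant in the two values; `theta = 0` gives 0.5.
#'
#' @param v_a,v_b option values (euros).
#' @param theta inverse temperature (per euro), `>= 0`.
#' @return probability of choosing option A, in `[0, 1]`.
#' @export
softmax_prob <- function(v_a, v_b, theta) {
  if (any(theta < 0)) stop("`theta` must be >= 0", call. = FALSE)
  stats::plogis(theta * (v_a - v_b))
}

# Rate for a category under hyperbolic families; configuration error if the
# family has no active rate for it.
category_rate <- function(params, category) {
  k <- c(reward = unname(params$k_R), effort = unname(params$k_E),
         punishment = unname(params$k_P))
  bad <- !(category %in% CATEGORIES)
  if (any(bad)) {
    stop_config("unknown category: ", paste(unique(category[bad]), collapse = ", "))
  }
  out <- unname(k[category])
  if (any(!is.finite(out))) {
    stop_config("family '", params$family, "' has no active discount rate for category: ",
                paste(unique(category[!is.finite(out)]), collapse = ", "))
  }
  out
}

#' Discounted option value under a parameter set
#'
#' Dispatches on the parameter family. For hyperbolic families the
#' category picks the rate; present-bias and beta-delta apply the same
#' discount to all categories.
#'
#' @param amount undiscounted amount in euros.
#' @param delay delay in days.
#' @param category `"reward"`, `"effort"` or `"punishment"`.
#' @param params a [discount_params()] object.
#' @export
discounted_value <- function(amount, delay, category, params) {
  switch(params$family,
    hyperbolic_specific = ,
    hyperbolic_shared = hyperbolic_value(amount, category_rate(params, category), delay),
    present_bias = present_bias_value(amount, params$beta, delay),
    quasi_hyperbolic = quasi_hyperbolic_value(amount, params$beta, params$delta, delay)
  )
}

#' Probability of choosing the later option of an intertemporal trial
#'
#' Each trial pairs a sooner/lower and a later/greater quantity of the
#' same item. Discounted values enter the softmax signed by desirability:
#' a reward's value counts positively, an effort's or punishment's
#' discounted cost counts negatively (a delayed cost is the more
#' attractive one). Increasing the effort rate `k_E` therefore raises the
#' probability of choosing the later effort.
#'
#' @param trials data frame with columns `category`, `unit_value`,
#'   `q_sooner`, `delay_sooner`, `q_later`, `delay_later`.
#' @param params a [discount_params()] object.
#' @return vector of probabilities of the later option, in `(0, 1)`.
#' @export
choice_probability <- function(trials, params) {
  required <- c("category", "unit_value", "q_sooner", "delay_sooner",
                "q_later", "delay_later")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop_config("trials table is missing column(s): ", paste(missing, collapse = ", "))
  }
  v_sooner <- discounted_value(trials$q_sooner * trials$unit_value,
                               trials$delay_sooner, trials$category, params)
  v_later <- discounted_value(trials$q_later * trials$unit_value,
                              trials$delay_later, trials$category, params)
  sign <- ifelse(trials$category == "reward", 1, -1)
  softmax_prob(sign * v_later, sign * v_sooner, params$theta)
}
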