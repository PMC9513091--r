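# Trial-level likelihoods: intertemporal choices and now/tomorrow choices.

#' Log-likelihood of intertemporal choices
#'
#' Sum of Bernoulli log-probabilities of the observed picks under the
#' discounting family in `params`. Probabilities are clipped away from
#' 0/1 (at 1e-12) so the result stays finite under extreme inverse
#' temperatures.
#'
#' @param trials data frame as in [choice_probability()], plus a
#'   `chose_later` indicator column (0/1).
#' @param params a [discount_params()] object.
#' @return scalar log-likelihood (`<= 0`).
#' @export
intertemporal_loglik <- function(trials, params) {
  if (nrow(trials) == 0L) stop("empty trial list", call. = FALSE)
  if (!"chose_later" %in% names(trials)) {
    stop_config("trials table is missing column(s): chose_later")
  }
  p <- clip_prob(choice_probability(trials, params))
  sum(ifelse(trials$chose_later == 1, log(p), log1p(-p)))
}

#' Net value of doing a task now or tomorrow
#'
#' `V = N_R R_i / (1 + k_R D) - N_E E_j / (1 + k_E D)`: discounted
#' benefit of the reward minus discounted cost of the effort, with the
#' same delay `D` applied to both components. `D` is 0 for the "now"
#' option and 1 for the "tomorrow" option.
#'
#' @param N_R,N_E quantities of reward and effort on offer.
#' @param R_i,E_j per-unit gain and loss equivalents (euros per unit).
#' @param k_R,k_E hyperbolic discount rates per day.
#' @param D delay in days, 0 (now) or 1 (tomorrow).
#' @param D_effort optional separate delay for the effort component (a
#'   generalization of the shared-delay first approximation); defaults
#'   to `D`.
#' @return net value in euros.
#' @export
now_tomorrow_net_value <- function(N_R, R_i, N_E, E_j, k_R, k_E, D,
                                   D_effort = D) {
  if (!all(D %in% c(0, 1)) || !all(D_effort %in% c(0, 1))) {
    stop("`D` must be 0 (now) or 1 (tomorrow)", call. = FALSE)
  }
  hyperbolic_value(N_R * R_i, k_R, D) - hyperbolic_value(N_E * E_j, k_E, D_effort)
}

#' Probability of choosing "tomorrow"
#'
#' Softmax comparison of the tomorrow (`D = 1`) and now (`D = 0`) net
#' values of the offer. The discount rates are fixed inputs (rigidly
#' incorporated from the intertemporal-choice fits); only `theta` scales
#' the comparison.
#'
#' @param trials data frame with columns `N_R`, `R_i`, `N_E`, `E_j`.
#' @param k_R,k_E fixed discount rates per day.
#' @param theta inverse temperature.
#' @return vector of probabilities of the tomorrow option.
#' @export
now_tomorrow_prob <- function(trials, k_R, k_E, theta) {
  required <- c("N_R", "R_i", "N_E", "E_j")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop_config("now/tomorrow table is missing column(s): ", paste(missing, collapse = ", "))
  }
  v_now <- now_tomorrow_net_value(trials$N_R, trials$R_i, trials$N_E, trials$E_j,
                                  k_R, k_E, 0)
  v_tom <- now_tomorrow_net_value(trials$N_R, trials$R_i, trials$N_E, trials$E_j,
                                  k_R, k_E, 1)
  softmax_prob(v_tom, v_now, theta)
}

#' Log-likelihood of now/tomorrow choices
#'
#' @param trials data frame as in [now_tomorrow_prob()], plus a
#'   `chose_tomorrow` indicator column (0/1).
#' @inheritParams now_tomorrow_prob
#' @return scalar log-likelihood.
#' @export
now_tomorrow_loglik <- function(trials, k_R, k_E, theta) {
  if (nrow(trials) == 0L) stop("empty trial list", call. = FALSE)
  if (!"chose_tomorrow" %in% names(trials)) {
    stop_config("now/tomorrow table is missing column(s): chose_tomorrow")
  }
  p <- clip_prob(now_tomorrow_prob(trials, k_R, k_E, theta))
  sum(ifelse(trials$chose_tomorrow == 1, log(p), log1p(-p)))
}

#' Procrastination level
#'
#' Selection frequency of the "tomorrow" option over a participant's
#' now/tomorrow trials.
#'
#' @param chose_tomorrow 0/1 indicator vector of tomorrow picks.
#' @return fraction in `[0, 1]`.
#' @export
procrastination_level <- function(chose_tomorrow) {
  if (length(chose_tomorrow) == 0L) stop("no trials", call. = FALSE)
  if (!all(chose_tomorrow %in% c(0, 1))) {
    stop("`chose_tomorrow` must be 0/1", call. = FALSE)
  }
  mean(chose_tomorrow)
}
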