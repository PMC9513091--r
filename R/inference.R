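# MAP estimation with Laplace-approximated log model evidence,
# model comparison, and fit diagnostics.

#' MAP fit with Laplace-approximated log model evidence
#'
#' Maximizes `loglik_fn(x) + log N(x; prior_mean, prior_sd)` over an
#' unconstrained parameter vector `x` (callers handle any log/logit
#' transforms and evaluate their likelihood on the natural scale). The
#' optimum is sought from `n_restarts` starting points: the prior mean
#' plus draws from the prior, so the search is deterministic given
#' `seed`. The log model evidence is the Laplace value
#' `logpost(MAP) + (p/2) log 2*pi - 0.5 log det H`, with `H` the Hessian
#' of the negative log posterior at the MAP (central finite differences).
#' A non-positive-definite Hessian is jittered and flagged rather than
#' raising an error; non-convergence is flagged, not thrown.
#'
#' With zero free parameters the evidence equals the log-likelihood
#' exactly; with zero data the MAP equals the prior mean.
#'
#' @param loglik_fn function of the parameter vector returning a scalar
#'   log-likelihood.
#' @param prior_mean,prior_sd Gaussian prior means and SDs (same length
#'   as the parameter vector; length 0 for a parameter-free model).
#' @param n_restarts number of optimization starts.
#' @param seed integer seed controlling the restart draws.
#' @param par_names optional parameter names.
#' @return object of class `map_fit`: `par` (MAP), `loglik`,
#'   `log_posterior`, `log_evidence`, `hessian`, `converged`, `flags`.
#' @export
fit_map <- function(loglik_fn, prior_mean, prior_sd, n_restarts = 10,
                    seed = 1, par_names = NULL) {
  p <- length(prior_mean)
  if (length(prior_sd) != p) stop("prior mean/sd length mismatch", call. = FALSE)
  if (p > 0 && any(prior_sd <= 0)) stop("prior SDs must be > 0", call. = FALSE)

  if (p == 0L) {
    ll <- loglik_fn(numeric(0))
    return(structure(list(
      par = stats::setNames(numeric(0), par_names), loglik = ll,
      log_posterior = ll, log_evidence = ll,
      hessian = matrix(numeric(0), 0, 0), converged = TRUE, flags = character(0)
    ), class = "map_fit"))
  }

  log_post <- function(x) {
    ll <- loglik_fn(x)
    if (!is.finite(ll)) return(-Inf)
    ll + sum(stats::dnorm(x, prior_mean, prior_sd, log = TRUE))
  }
  neg <- function(x) {
    lp <- log_post(x)
    if (!is.finite(lp)) 1e12 else -lp
  }

  starts <- with_seed(seed, {
    s <- matrix(stats::rnorm((n_restarts - 1) * p, rep(prior_mean, each = n_restarts - 1),
                             rep(prior_sd, each = n_restarts - 1)),
                ncol = p)
    rbind(matrix(prior_mean, nrow = 1), s)
  })

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], neg, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      res <- tryCatch(
        stats::optim(starts[i, ], neg, method = "Nelder-Mead",
                     control = list(maxit = 2000)),
        error = function(e) NULL
      )
    }
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  flags <- character(0)
  if (is.null(best)) {
    best <- list(par = prior_mean, value = neg(prior_mean), convergence = 1L)
    flags <- c(flags, "optimization_failed")
  }
  converged <- identical(best$convergence, 0L)
  if (!converged) flags <- union(flags, "not_converged")

  par <- best$par
  H <- tryCatch(pracma::hessian(neg, par), error = function(e) NULL)
  if (is.null(H) || any(!is.finite(H))) {
    H <- diag(1 / prior_sd^2, p)
    flags <- c(flags, "hessian_fallback_prior")
  }
  H <- (H + t(H)) / 2
  ld <- log_det_pd(H)
  if (!is.null(ld$flag)) flags <- c(flags, ld$flag)

  lp_map <- log_post(par)
  ll_map <- loglik_fn(par)
  evidence <- lp_map + (p / 2) * log(2 * pi) - 0.5 * ld$logdet
  if (!is.null(par_names)) names(par) <- par_names

  structure(list(
    par = par, loglik = ll_map, log_posterior = lp_map,
    log_evidence = evidence, hessian = ld$H, converged = converged, flags = flags
  ), class = "map_fit")
}

# log-determinant of a (regularized) positive-definite matrix; jitters the
# diagonal until Cholesky succeeds and reports a flag if it had to.
log_det_pd <- function(H) {
  jitter <- 0
  for (i in 0:8) {
    Hj <- H + diag(jitter, nrow(H))
    ch <- tryCatch(chol(Hj), error = function(e) NULL)
    if (!is.null(ch)) {
      return(list(logdet = 2 * sum(log(diag(ch))), H = Hj,
                  flag = if (jitter > 0) "hessian_regularized" else NULL))
    }
    jitter <- if (jitter == 0) 1e-8 else jitter * 10
  }
  list(logdet = sum(log(abs(diag(H)) + 1)), H = H, flag = "hessian_singular")
}

#' @export
print.map_fit <- function(x, ...) {
  cat("<map_fit>", length(x$par), "parameter(s);",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (length(x$par)) print(round(x$par, 4))
  cat(sprintf("  loglik %.3f  log evidence %.3f\n", x$loglik, x$log_evidence))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Log model evidence of a fit
#'
#' @param fit a `map_fit` object.
#' @return scalar Laplace log evidence.
#' @export
log_evidence <- function(fit) {
  stopifnot(inherits(fit, "map_fit"))
  fit$log_evidence
}

# --- family-specific fits ---------------------------------------------------

# Working-scale parameterization per family. Rates k are fitted on the
# native scale (keeping their stated Gaussian priors literal, with the
# hyperbolic denominator guard enforced through the likelihood); theta on
# the log scale and beta/delta on the logit scale, each with a standard
# normal working-scale prior (prior median theta = 1, beta = delta = 0.5).
family_parameterization <- function(family, categories, max_delay = 30) {
  categories <- intersect(CATEGORIES, unique(categories))
  if (!length(categories)) stop_config("no known categories in trials")
  switch(family,
    hyperbolic_specific = {
      knames <- paste0("k_", c(reward = "R", effort = "E", punishment = "P")[categories])
      list(
        names = c(knames, "log_theta"),
        mean = c(rep(0, length(knames)), 0),
        sd = rep(1, length(knames) + 1),
        to_params = function(x) {
          kk <- stats::setNames(rep(NA_real_, 3), c("k_R", "k_E", "k_P"))
          kk[knames] <- x[seq_along(knames)]
          list(k_R = kk[["k_R"]], k_E = kk[["k_E"]], k_P = kk[["k_P"]],
               theta = exp(x[length(x)]), beta = NA_real_, delta = NA_real_,
               family = "hyperbolic_specific", max_delay = max_delay)
        }
      )
    },
    hyperbolic_shared = list(
      names = c("k", "log_theta"), mean = c(0, 0), sd = c(1, 1),
      to_params = function(x) {
        list(k_R = x[1], k_E = x[1], k_P = x[1], theta = exp(x[2]),
             beta = NA_real_, delta = NA_real_,
             family = "hyperbolic_shared", max_delay = max_delay)
      }
    ),
    present_bias = list(
      names = c("logit_beta", "log_theta"), mean = c(0, 0), sd = c(1, 1),
      to_params = function(x) {
        list(k_R = NA_real_, k_E = NA_real_, k_P = NA_real_,
             theta = exp(x[2]), beta = stats::plogis(x[1]), delta = NA_real_,
             family = "present_bias", max_delay = max_delay)
      }
    ),
    # the prior on logit(delta) is centered high (median delta = 0.9):
    # delta is a *daily* exponential factor, so values near 1 are the
    # a-priori plausible regime (delta = 0.5 would wipe out any outcome
    # beyond a couple of days)
    quasi_hyperbolic = list(
      names = c("logit_beta", "logit_delta", "log_theta"),
      mean = c(0, 2.2, 0), sd = c(1, 1, 1),
      to_params = function(x) {
        list(k_R = NA_real_, k_E = NA_real_, k_P = NA_real_,
             theta = exp(x[3]), beta = stats::plogis(x[1]),
             delta = stats::plogis(x[2]),
             family = "quasi_hyperbolic", max_delay = max_delay)
      }
    ),
    stop_config("unknown family: ", family)
  )
}

# Evaluate intertemporal loglik under working-scale x; -Inf outside the
# hyperbolic guard region.
family_loglik_fn <- function(trials, parmz) {
  max_d <- max(trials$delay_sooner, trials$delay_later)
  function(x) {
    pl <- parmz$to_params(x)
    ks <- c(pl$k_R, pl$k_E, pl$k_P)
    if (any(is.finite(ks) & (1 + ks * max_d) <= 1e-6)) return(-Inf)
    params <- structure(pl, class = "discount_params")
    intertemporal_loglik(trials, params)
  }
}

#' Fit a discounting model to one participant's intertemporal choices
#'
#' MAP estimation (see [fit_map()]) of the chosen family on all trials of
#' one participant, across whichever outcome categories are present.
#' Priors: standard normal on native-scale rates, on `log(theta)` and on
#' `logit(beta)`/`logit(delta)`.
#'
#' @param trials one participant's trials (see [intertemporal_loglik()]).
#' @param family discounting family tag (see [discount_params()]).
#' @param n_restarts,seed passed to [fit_map()].
#' @return a `map_fit` with a `params` element holding natural-scale
#'   [discount_params()].
#' @export
fit_discounting <- function(trials, family = DISCOUNT_FAMILIES,
                            n_restarts = 10, seed = 1) {
  family <- match.arg(family, DISCOUNT_FAMILIES)
  if (nrow(trials) == 0L) stop("empty trial list", call. = FALSE)
  max_d <- max(trials$delay_sooner, trials$delay_later, 30)
  parmz <- family_parameterization(family, trials$category, max_delay = max_d)
  fit <- fit_map(family_loglik_fn(trials, parmz), parmz$mean, parmz$sd,
                 n_restarts = n_restarts, seed = seed, par_names = parmz$names)
  fit$family <- family
  fit$params <- structure(parmz$to_params(unname(fit$par)), class = "discount_params")
  fit
}

#' Fit the now/tomorrow choice model (inverse temperature only)
#'
#' The discount rates and unit values are rigidly incorporated from the
#' intertemporal-choice stage; the only free parameter is `theta`,
#' fitted on the log scale with a standard normal prior.
#'
#' @param trials one participant's now/tomorrow trials.
#' @param k_R,k_E fixed discount rates.
#' @param n_restarts,seed passed to [fit_map()].
#' @return a `map_fit` with a `theta` element (natural scale).
#' @export
fit_now_tomorrow <- function(trials, k_R, k_E, n_restarts = 10, seed = 1) {
  ll <- function(x) now_tomorrow_loglik(trials, k_R, k_E, exp(x[1]))
  fit <- fit_map(ll, 0, 1, n_restarts = n_restarts, seed = seed,
                 par_names = "log_theta")
  fit$theta <- exp(fit$par[[1]])
  fit
}

# --- model comparison -------------------------------------------------------

#' Group-level Bayesian model comparison
#'
#' Sums per-participant log evidences within each model family and
#' reports pairwise differences as log group Bayes factors (fixed-effects
#' comparison).
#'
#' @param evidence data frame with columns `participant_id`, `family`,
#'   `log_evidence`; every family must cover the same participants.
#' @return list with `group_evidence` (named vector, decreasing),
#'   `log_group_bf` (matrix of row minus column differences) and
#'   `best_family`.
#' @export
compare_models <- function(evidence) {
  required <- c("participant_id", "family", "log_evidence")
  missing <- setdiff(required, names(evidence))
  if (length(missing)) {
    stop_config("evidence table is missing column(s): ", paste(missing, collapse = ", "))
  }
  sets <- tapply(evidence$participant_id, evidence$family,
                 function(x) paste(sort(unique(x)), collapse = "|"))
  if (length(unique(sets)) != 1L) {
    stop_config("participant sets differ across families")
  }
  tot <- tapply(evidence$log_evidence, evidence$family, sum)
  tot <- sort(tot, decreasing = TRUE)
  bf <- outer(tot, tot, "-")
  dimnames(bf) <- list(names(tot), names(tot))
  list(group_evidence = tot, log_group_bf = bf, best_family = names(tot)[1])
}

# --- diagnostics ------------------------------------------------------------

#' Balanced accuracy of binary choice predictions
#'
#' Average of the per-class accuracies of thresholding the modeled
#' probabilities at 0.5, computed separately for the two choice types.
#' A predicted probability of exactly 0.5 counts as half correct. If only
#' one class is present the single-class accuracy is returned with a
#' `"single_class"` flag attribute.
#'
#' @param prob modeled probabilities of choosing option 1.
#' @param chose observed 0/1 choices.
#' @return balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(prob, chose) {
  if (length(prob) == 0L) stop("empty input", call. = FALSE)
  if (length(prob) != length(chose)) stop("length mismatch", call. = FALSE)
  correct <- ifelse(prob == 0.5, 0.5, as.numeric((prob > 0.5) == (chose == 1)))
  classes <- unique(chose)
  if (length(classes) == 1L) {
    out <- mean(correct)
    attr(out, "flags") <- "single_class"
    return(out)
  }
  mean(c(mean(correct[chose == 1]), mean(correct[chose == 0])))
}

#' Calibration bins for choice probabilities
#'
#' Divides trials into `n_bins` equal-count bins of increasing modeled
#' probability and returns the per-bin mean modeled probability and mean
#' observed choice rate. With fewer trials than bins, one-trial bins are
#' used and the result is flagged; identical probabilities throughout
#' collapse to a single flagged bin.
#'
#' @inheritParams balanced_accuracy
#' @param n_bins number of bins (default 8).
#' @return data frame `bin`, `n`, `mean_modeled`, `mean_observed`, with a
#'   `flags` attribute when degenerate.
#' @export
calibration_bins <- function(prob, chose, n_bins = 8) {
  if (length(prob) == 0L) stop("empty input", call. = FALSE)
  if (length(prob) != length(chose)) stop("length mismatch", call. = FALSE)
  flags <- character(0)
  n <- length(prob)
  if (stats::sd(prob) == 0) {
    out <- data.frame(bin = 1L, n = n, mean_modeled = prob[1],
                      mean_observed = mean(chose))
    attr(out, "flags") <- "degenerate_probabilities"
    return(out)
  }
  if (n < n_bins) {
    n_bins <- n
    flags <- c(flags, "fewer_bins_than_requested")
  }
  ord <- order(prob)
  bin_of <- ceiling(seq_along(ord) / n * n_bins)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    idx <- ord[bin_of == b]
    data.frame(bin = b, n = length(idx), mean_modeled = mean(prob[idx]),
               mean_observed = mean(chose[idx]))
  }))
  if (length(flags)) attr(out, "flags") <- flags
  out
}
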