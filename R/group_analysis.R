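# Group-level regression layer: per-participant logistic regressions of
# choice factors, cross-participant regressions of procrastination on
# discount-rate estimates, and correlations between measures.

# Ridge-stabilized logistic fit used when glm reports separation.
ridge_logistic <- function(X, y, lambda = 1) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(-ifelse(y == 1, eta, -eta)))) + lambda / 2 * sum(b[-1]^2)
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 500))$par
}

#' Per-participant logistic regressions of choice factors
#'
#' Regresses each participant's choices on standardized experimental
#' factors, then tests each coefficient against zero across participants
#' with one-sample t tests. For intertemporal trials the factors are the
#' difference in undiscounted value (or cost) and the difference in delay
#' between the later and sooner options; for now/tomorrow trials, the
#' reward value and effort cost on offer. Perfectly separated fits are
#' ridge-stabilized and flagged.
#'
#' @param trials trial table covering one or more participants
#'   (intertemporal: see [choice_probability()] plus `chose_later`;
#'   now/tomorrow: see [now_tomorrow_prob()] plus `chose_tomorrow`).
#' @param task `"intertemporal"` or `"now_tomorrow"`.
#' @return list with `coefficients` (one row per participant) and
#'   `group` (per factor: mean coefficient, t, df, p).
#' @export
logistic_choice_factors <- function(trials, task = c("intertemporal", "now_tomorrow")) {
  task <- match.arg(task)
  if (task == "intertemporal") {
    response <- "chose_later"
    design <- function(d) data.frame(
      rel_value = d$q_later * d$unit_value - d$q_sooner * d$unit_value,
      rel_delay = d$delay_later - d$delay_sooner
    )
  } else {
    response <- "chose_tomorrow"
    design <- function(d) data.frame(
      reward_value = d$N_R * d$R_i,
      effort_cost = d$N_E * d$E_j
    )
  }
  if (!response %in% names(trials)) {
    stop_config("trials table is missing column(s): ", response)
  }
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(pid) {
    d <- trials[trials$participant_id == pid, , drop = FALSE]
    Xd <- design(d)
    Xs <- as.data.frame(lapply(Xd, function(x) {
      s <- stats::sd(x)
      if (s > 0) (x - mean(x)) / s else x - mean(x)
    }))
    y <- d[[response]]
    flagged <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = cbind(y = y, Xs), family = stats::binomial()),
      warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    co <- stats::coef(fit)
    if (flagged || any(!is.finite(co)) || any(abs(co) > 15)) {
      X <- cbind(1, as.matrix(Xs))
      co <- ridge_logistic(X, y)
      names(co) <- c("(Intercept)", names(Xs))
      flagged <- TRUE
    }
    out <- data.frame(participant_id = pid, t(co), check.names = FALSE,
                      stringsAsFactors = FALSE)
    out$ridge_stabilized <- flagged
    out
  })
  coefs <- do.call(rbind, rows)
  factors <- setdiff(names(coefs), c("participant_id", "(Intercept)", "ridge_stabilized"))
  group <- do.call(rbind, lapply(factors, function(f) {
    tt <- stats::t.test(coefs[[f]])
    data.frame(factor = f, mean = unname(tt$estimate), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value, stringsAsFactors = FALSE)
  }))
  list(coefficients = coefs, group = group)
}

#' Cross-participant regression of procrastination on time preferences
#'
#' OLS regression of a procrastination measure — the tomorrow-choice
#' frequency (`outcome = "lab"`) or the form-return delay
#' (`outcome = "home"`, never-returners excluded) — on discount-rate
#' estimates plus age and gender. Predictors are z-scored so
#' coefficients are comparable across rate scales; rates enter on the
#' log scale by default (they are right-skewed).
#'
#' @param summaries participant summary table with columns `id`, `k_R`,
#'   `k_E`, `procrastination_level`, `form_delay` (NA if never
#'   returned), `age`, `gender`.
#' @param outcome `"lab"` or `"home"`.
#' @param predictors names of the predictor columns.
#' @param log_rates take `log` of `k_*` predictors first.
#' @return data frame of coefficients with `estimate`, `t`, `df`, `p`,
#'   plus attributes `r_squared` and `n`.
#' @export
regress_procrastination <- function(summaries, outcome = c("lab", "home"),
                                    predictors = c("k_R", "k_E", "age", "gender"),
                                    log_rates = TRUE) {
  outcome <- match.arg(outcome)
  yvar <- if (outcome == "lab") "procrastination_level" else "form_delay"
  need <- c(yvar, predictors)
  missing <- setdiff(need, names(summaries))
  if (length(missing)) {
    stop_config("summaries table is missing column(s): ", paste(missing, collapse = ", "))
  }
  d <- summaries[stats::complete.cases(summaries[, need, drop = FALSE]), , drop = FALSE]
  X <- d[, predictors, drop = FALSE]
  if (log_rates) {
    for (nm in grep("^k_", predictors, value = TRUE)) X[[nm]] <- log(X[[nm]])
  }
  keep <- vapply(X, function(x) stats::sd(x) > 0, logical(1))
  X <- as.data.frame(lapply(X[keep], function(x) (x - mean(x)) / stats::sd(x)))
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < ncol(X) + 1) {
    drop_idx <- setdiff(seq_len(ncol(X) + 1), qrX$pivot[seq_len(qrX$rank)])
    stop_config("collinear predictor column(s): ",
                paste(c("(Intercept)", names(X))[drop_idx], collapse = ", "))
  }
  df_fit <- cbind(y = d[[yvar]], X)
  fit <- stats::lm(y ~ ., data = df_fit)
  sm <- summary(fit)
  co <- sm$coefficients
  out <- data.frame(term = rownames(co), estimate = co[, 1], t = co[, 3],
                    df = fit$df.residual, p = co[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "r_squared") <- sm$r.squared
  attr(out, "n") <- nrow(d)
  out
}

#' Pairwise Pearson correlations between participant measures
#'
#' @param summaries participant summary table.
#' @param vars columns to correlate (numeric).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`; one-tailed
#'   tests are the convention when the direction of an association
#'   between two measures of the same construct is fixed a priori.
#' @return data frame `var1`, `var2`, `n`, `r`, `p`.
#' @export
measure_correlations <- function(summaries, vars,
                                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  missing <- setdiff(vars, names(summaries))
  if (length(missing)) {
    stop_config("summaries table is missing column(s): ", paste(missing, collapse = ", "))
  }
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    d <- summaries[stats::complete.cases(summaries[, pr]), pr]
    if (nrow(d) < 3) stop_config("fewer than 3 complete pairs for ",
                                 pr[1], " vs ", pr[2])
    ct <- stats::cor.test(d[[1]], d[[2]], alternative = alternative)
    data.frame(var1 = pr[1], var2 = pr[2], n = nrow(d),
               r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
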