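# Population-level drivers tying the modules together, plus the command
# line entry point.

#' Fit a discounting family to every participant in a trial table
#'
#' @param trials intertemporal trial table covering several participants.
#' @param family discounting family tag.
#' @param n_restarts,seed passed to [fit_discounting()]; each
#'   participant's fit is seeded deterministically from `seed`.
#' @return data frame with one row per participant: natural-scale
#'   parameter estimates, log-likelihood, Laplace log evidence, balanced
#'   accuracy and convergence flag. The `map_fit` objects are attached
#'   as the `fits` attribute.
#' @export
fit_population_discounting <- function(trials, family = "hyperbolic_specific",
                                       n_restarts = 10, seed = 1) {
  ids <- unique(trials$participant_id)
  fits <- lapply(seq_along(ids), function(i) {
    d <- trials[trials$participant_id == ids[i], , drop = FALSE]
    fit_discounting(d, family = family, n_restarts = n_restarts,
                    seed = seed + i)
  })
  rows <- lapply(seq_along(ids), function(i) {
    f <- fits[[i]]
    d <- trials[trials$participant_id == ids[i], , drop = FALSE]
    p <- choice_probability(d, f$params)
    data.frame(
      participant_id = ids[i], family = family,
      k_R = f$params$k_R, k_E = f$params$k_E, k_P = f$params$k_P,
      theta = f$params$theta, beta = f$params$beta, delta = f$params$delta,
      loglik = f$loglik, log_evidence = f$log_evidence,
      balanced_accuracy = as.numeric(balanced_accuracy(p, d$chose_later)),
      converged = f$converged, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' Group-level comparison of discounting families on one trial table
#'
#' Fits every family to every participant and compares summed log
#' evidences (see [compare_models()]).
#'
#' @inheritParams fit_population_discounting
#' @param families character vector of family tags.
#' @return list with `evidence` (long data frame), `comparison` (from
#'   [compare_models()]).
#' @export
compare_discounting_families <- function(trials,
                                         families = DISCOUNT_FAMILIES,
                                         n_restarts = 10, seed = 1) {
  evidence <- do.call(rbind, lapply(families, function(fam) {
    df <- fit_population_discounting(trials, family = fam,
                                     n_restarts = n_restarts, seed = seed)
    data.frame(participant_id = df$participant_id, family = fam,
               log_evidence = df$log_evidence, stringsAsFactors = FALSE)
  }))
  list(evidence = evidence, comparison = compare_models(evidence))
}

#' Group-level comparison of the static and dynamic completion models
#'
#' For each participant, fits the completion-softmax inverse temperature
#' of both models to the observed form-return delay (discount rates,
#' reward and cost held fixed) and sums the Laplace log evidences.
#'
#' @param summaries data frame with columns `id`, `k_R`, `k_E`,
#'   `compensation`, `form_cost`, `form_delay` (NA rows are dropped).
#' @param deadline days.
#' @param normalize value normalization.
#' @param n_restarts,seed passed to [fit_delay_model()].
#' @return list with `evidence` (per participant and model),
#'   `group_evidence`, and `log_bf_dynamic_vs_static`.
#' @export
compare_delay_models <- function(summaries, deadline = 30,
                                 normalize = "max_abs",
                                 n_restarts = 5, seed = 1) {
  d <- summaries[!is.na(summaries$form_delay), , drop = FALSE]
  if (nrow(d) == 0) stop_config("no participants with an observed form delay")
  rows <- list()
  for (model in c("dynamic", "static_softmax")) {
    ev <- vapply(seq_len(nrow(d)), function(i) {
      task <- procrastination_task(d$compensation[i], d$form_cost[i],
                                   d$k_R[i], d$k_E[i], theta = 0.5,
                                   deadline = deadline)
      fit_delay_model(task, d$form_delay[i], model = model,
                      normalize = normalize, n_restarts = n_restarts,
                      seed = seed + i)$log_evidence
    }, numeric(1))
    rows[[model]] <- data.frame(id = d$id, model = model, log_evidence = ev,
                                stringsAsFactors = FALSE)
  }
  evidence <- do.call(rbind, rows)
  group <- tapply(evidence$log_evidence, evidence$model, sum)
  list(evidence = evidence, group_evidence = group,
       log_bf_dynamic_vs_static = unname(group["dynamic"] - group["static_softmax"]))
}

#' Generate a full synthetic data set
#'
#' Runs the whole generative chain: population, ratings, unit values,
#' intertemporal choice sets and choices per category (under the
#' category-specific hyperbolic truth), now/tomorrow offers and choices,
#' and form-return delays under the dynamic completion model.
#'
#' @param spec a [population_spec()].
#' @param n_trials_per_category intertemporal trials per category.
#' @param n_now_tomorrow_trials now/tomorrow offers per participant.
#' @param home_theta inverse temperature of the home-task simulation.
#' @return list of class `synthetic_dataset`: `population`,
#'   `unit_values`, `trials`, `now_tomorrow`, `form_delays`.
#' @export
generate_dataset <- function(spec = population_spec(),
                             n_trials_per_category = 60,
                             n_now_tomorrow_trials = 150,
                             home_theta = 0.5) {
  pop <- generate_population(spec)
  uv <- unit_values_from_ratings(pop$ratings)
  parts <- pop$participants
  trials <- list(); nt <- list()
  for (i in seq_len(nrow(parts))) {
    pid <- parts$id[i]
    uvi <- uv[uv$participant_id == pid, , drop = FALSE]
    truth <- discount_params(k_R = parts$k_R[i], k_E = parts$k_E[i],
                             k_P = parts$k_P[i], theta = parts$theta[i],
                             family = "hyperbolic_specific")
    for (cat in CATEGORIES) {
      k_apriori <- exp(spec[[paste0("k_", c(reward = "R", effort = "E",
                                            punishment = "P")[cat], "_dist")]][1])
      cs <- generate_choice_set(uvi, cat, n_trials = n_trials_per_category,
                                a_priori_k = k_apriori,
                                seed = spec$seed + 1000 + i * 7 +
                                  match(cat, CATEGORIES),
                                participant_id = pid)
      trials[[paste(pid, cat)]] <- simulate_choices(cs, truth,
                                                    seed = spec$seed + 2000 + i * 7 +
                                                      match(cat, CATEGORIES))
    }
    offers <- generate_now_tomorrow_set(uvi, n_trials = n_now_tomorrow_trials,
                                        seed = spec$seed + 3000 + i,
                                        participant_id = pid)
    nt[[pid]] <- simulate_now_tomorrow_choices(offers, parts$k_R[i], parts$k_E[i],
                                               parts$theta[i],
                                               seed = spec$seed + 4000 + i)
  }
  delays <- simulate_form_delays(pop, model = "dynamic", theta = home_theta,
                                 seed = spec$seed + 5000)
  structure(list(population = pop, unit_values = uv,
                 trials = do.call(rbind, trials),
                 now_tomorrow = do.call(rbind, nt),
                 form_delays = delays),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>", nrow(x$population$participants), "participants;",
      nrow(x$trials), "intertemporal trials;", nrow(x$now_tomorrow),
      "now/tomorrow trials\n")
  invisible(x)
}

# --- command line interface -------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: procrastinatr <subcommand> [--config FILE] [--seed N] [--outdir DIR]",
    "subcommands:",
    "  synth            generate a synthetic data set (CSV + ground-truth JSON)",
    "  fit-discounting  fit the first configured family per participant",
    "  compare-models   fit all configured families and compare evidence",
    "  fit-now-tomorrow fit the now/tomorrow inverse temperature",
    "  predict-delay    completion-time distributions for the home task",
    "  simulate-grid    mean completion delay over the discount-rate plane",
    "  group-analysis   cross-participant regressions and correlations",
    "  report           plain-text summary of a run directory",
    sep = "\n"
  )
}

parse_cli_args <- function(args) {
  out <- list(subcommand = args[1], config = NULL, seed = NULL, outdir = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- args[i]
    if (!key %in% c("--config", "--seed", "--outdir") || i == length(args)) {
      stop_config("unrecognized or incomplete option: ", key)
    }
    out[[sub("^--", "", key)]] <- args[i + 1]
    i <- i + 2
  }
  out
}

#' Command line entry point
#'
#' Dispatches the pipeline subcommands; see
#' `system.file("scripts", "procrastinatr", package = "procrastinatr")`
#' for the executable wrapper. Every subcommand writes its outputs plus
#' a JSON manifest (config hash, seed, package version) into the output
#' directory.
#'
#' @param args character vector of command line arguments.
#' @return integer exit status, invisibly (0 on success).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message(cli_usage())
    return(invisible(1L))
  }
  parsed <- tryCatch(parse_cli_args(args), error = function(e) e)
  if (inherits(parsed, "error")) {
    message(conditionMessage(parsed), "\n", cli_usage())
    return(invisible(1L))
  }
  cfg <- tryCatch(read_run_config(parsed$config), error = function(e) e)
  if (inherits(cfg, "error")) {
    message(conditionMessage(cfg))
    return(invisible(1L))
  }
  if (!is.null(parsed$seed)) cfg$seed <- as.integer(parsed$seed)
  if (!is.null(parsed$outdir)) cfg$outdir <- parsed$outdir
  handler <- switch(parsed$subcommand,
    "synth" = cli_synth,
    "fit-discounting" = cli_fit_discounting,
    "compare-models" = cli_compare_models,
    "fit-now-tomorrow" = cli_fit_now_tomorrow,
    "predict-delay" = cli_predict_delay,
    "simulate-grid" = cli_simulate_grid,
    "group-analysis" = cli_group_analysis,
    "report" = cli_report,
    NULL
  )
  if (is.null(handler)) {
    message("unknown subcommand: ", parsed$subcommand, "\n", cli_usage())
    return(invisible(1L))
  }
  status <- tryCatch({ handler(cfg); 0L }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_log <- function(...) message(format(Sys.time(), "[%H:%M:%S] "), ...)

cli_synth <- function(cfg) {
  spec <- population_spec(n_participants = cfg$n_participants,
                          deadline = cfg$deadline, seed = cfg$seed)
  ds <- generate_dataset(spec,
                         n_trials_per_category = cfg$n_trials_per_category,
                         n_now_tomorrow_trials = cfg$n_now_tomorrow_trials,
                         home_theta = cfg$home_theta)
  out <- cfg$outdir
  write_table(ds$population$ratings, file.path(out, "ratings.csv"))
  write_table(ds$unit_values, file.path(out, "unit_values.csv"))
  write_table(ds$trials, file.path(out, "choice_trials.csv"))
  write_table(ds$now_tomorrow, file.path(out, "now_tomorrow.csv"))
  write_table(ds$form_delays, file.path(out, "form_delays.csv"))
  truth <- ds$population$participants
  jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                       digits = NA, pretty = TRUE)
  write_manifest(out, cfg, cfg$seed)
  cli_log("synth: wrote ", nrow(ds$trials), " trials for ",
          nrow(truth), " participants to ", out)
}

cli_fit_discounting <- function(cfg) {
  if (is.null(cfg$trials)) stop_config("config key 'trials' is required")
  trials <- read_choice_trials(cfg$trials)
  fits <- fit_population_discounting(trials, family = cfg$families[[1]],
                                     n_restarts = cfg$n_restarts,
                                     seed = cfg$seed)
  write_table(fits, file.path(cfg$outdir, "discounting_fits.csv"))
  jsonlite::write_json(fits, file.path(cfg$outdir, "discounting_fits.json"),
                       digits = NA, pretty = TRUE)
  write_manifest(cfg$outdir, cfg, cfg$seed)
  cli_log("fit-discounting: ", nrow(fits), " participants, family ",
          cfg$families[[1]])
}

cli_compare_models <- function(cfg) {
  if (is.null(cfg$trials)) stop_config("config key 'trials' is required")
  trials <- read_choice_trials(cfg$trials)
  cmp <- compare_discounting_families(trials, families = cfg$families,
                                      n_restarts = cfg$n_restarts,
                                      seed = cfg$seed)
  write_table(cmp$evidence, file.path(cfg$outdir, "model_evidence.csv"))
  jsonlite::write_json(
    list(group_evidence = as.list(cmp$comparison$group_evidence),
         best_family = cmp$comparison$best_family),
    file.path(cfg$outdir, "model_comparison.json"), digits = NA, pretty = TRUE)
  write_manifest(cfg$outdir, cfg, cfg$seed)
  cli_log("compare-models: best family ", cmp$comparison$best_family)
}

cli_fit_now_tomorrow <- function(cfg) {
  if (is.null(cfg$now_tomorrow) || is.null(cfg$summaries)) {
    stop_config("config keys 'now_tomorrow' and 'summaries' are required")
  }
  nt <- read_now_tomorrow_trials(cfg$now_tomorrow)
  sm <- read_participant_summaries(cfg$summaries, deadline = cfg$deadline)
  rows <- list(); probs <- list()
  for (i in seq_len(nrow(sm))) {
    d <- nt[nt$participant_id == sm$id[i], , drop = FALSE]
    if (nrow(d) == 0) next
    fit <- fit_now_tomorrow(d, sm$k_R[i], sm$k_E[i],
                            n_restarts = cfg$n_restarts, seed = cfg$seed + i)
    p <- now_tomorrow_prob(d, sm$k_R[i], sm$k_E[i], fit$theta)
    rows[[sm$id[i]]] <- data.frame(
      id = sm$id[i], theta = fit$theta, log_evidence = fit$log_evidence,
      procrastination_level = procrastination_level(d$chose_tomorrow),
      balanced_accuracy = as.numeric(balanced_accuracy(p, d$chose_tomorrow)),
      stringsAsFactors = FALSE)
    probs[[sm$id[i]]] <- data.frame(id = sm$id[i], trial = d$trial,
                                    predicted_prob = p,
                                    chose_tomorrow = d$chose_tomorrow,
                                    stringsAsFactors = FALSE)
  }
  write_table(do.call(rbind, rows), file.path(cfg$outdir, "now_tomorrow_fits.csv"))
  write_table(do.call(rbind, probs),
              file.path(cfg$outdir, "now_tomorrow_predictions.csv"))
  write_manifest(cfg$outdir, cfg, cfg$seed)
  cli_log("fit-now-tomorrow: ", length(rows), " participants")
}

cli_predict_delay <- function(cfg) {
  if (is.null(cfg$summaries)) stop_config("config key 'summaries' is required")
  sm <- read_participant_summaries(cfg$summaries, deadline = cfg$deadline)
  need <- setdiff(c("compensation", "form_cost"), names(sm))
  if (length(need)) {
    stop_config("summaries table is missing column(s): ", paste(need, collapse = ", "))
  }
  sm$compensation <- as.numeric(sm$compensation)
  sm$form_cost <- as.numeric(sm$form_cost)
  rows <- lapply(seq_len(nrow(sm)), function(i) {
    task <- procrastination_task(sm$compensation[i], sm$form_cost[i],
                                 sm$k_R[i], sm$k_E[i],
                                 theta = cfg$home_theta, deadline = cfg$deadline)
    dist <- dynamic_completion_distribution(task,
                                            normalize = cfg$value_normalization)
    data.frame(id = sm$id[i], day = dist$day, daily_prob = dist$daily_prob,
               pmf = dist$pmf, cdf = dist$cdf,
               expected_delay = dist$expected_delay, stringsAsFactors = FALSE)
  })
  write_table(do.call(rbind, rows),
              file.path(cfg$outdir, "completion_distributions.csv"))
  write_manifest(cfg$outdir, cfg, cfg$seed)
  cli_log("predict-delay: ", nrow(sm), " participants")
}

cli_simulate_grid <- function(cfg) {
  grid <- simulate_duration_grid(n_samples = cfg$grid_n_samples,
                                 deadline = cfg$deadline,
                                 normalize = cfg$value_normalization,
                                 seed = cfg$seed)
  write_table(grid, file.path(cfg$outdir, "duration_grid.csv"))
  write_manifest(cfg$outdir, cfg, cfg$seed)
  cli_log("simulate-grid: ", nrow(grid), " cells from ",
          cfg$grid_n_samples, " samples")
}

cli_group_analysis <- function(cfg) {
  if (is.null(cfg$summaries)) stop_config("config key 'summaries' is required")
  sm <- read_participant_summaries(cfg$summaries, deadline = cfg$deadline)
  lab <- regress_procrastination(sm, "lab",
                                 log_rates = cfg$log_rates_in_regression)
  home <- regress_procrastination(sm, "home",
                                  log_rates = cfg$log_rates_in_regression)
  cors <- measure_correlations(sm, c("k_R", "k_E", "procrastination_level"),
                               alternative = "two.sided")
  lab$outcome <- "lab"; home$outcome <- "home"
  write_table(rbind(lab, home), file.path(cfg$outdir, "regressions.csv"))
  write_table(cors, file.path(cfg$outdir, "correlations.csv"))
  rpt <- c(
    "Group analysis",
    sprintf("  lab outcome: n = %d, R^2 = %.3f", attr(lab, "n"),
            attr(lab, "r_squared")),
    sprintf("  home outcome: n = %d, R^2 = %.3f", attr(home, "n"),
            attr(home, "r_squared"))
  )
  writeLines(rpt, file.path(cfg$outdir, "report.txt"))
  write_manifest(cfg$outdir, cfg, cfg$seed)
  cli_log("group-analysis: written to ", cfg$outdir)
}

cli_report <- function(cfg) {
  files <- list.files(cfg$outdir, pattern = "\\.(csv|json|txt)$")
  if (!length(files)) stop_config("no artifacts found in ", cfg$outdir)
  lines <- c("procrastinatr run directory: " , cfg$outdir,
             paste("  -", files))
  writeLines(lines, file.path(cfg$outdir, "summary.txt"))
  cli_log("report: ", length(files), " artifacts listed")
}
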