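# Tabular I/O with schema validation, run configuration, and manifests.

# Declared CSV schemas: column name -> type ("character" or "numeric").
TABLE_SCHEMAS <- list(
  ratings = c(participant_id = "character", item_id = "character",
              category = "character", subcategory = "character",
              q1 = "numeric", q5 = "numeric"),
  unit_values = c(participant_id = "character", item_id = "character",
                  category = "character", value_per_unit = "numeric"),
  choice_trials = c(participant_id = "character", trial = "numeric",
                    item_id = "character", category = "character",
                    unit_value = "numeric", q_sooner = "numeric",
                    delay_sooner = "numeric", q_later = "numeric",
                    delay_later = "numeric", chose_later = "numeric"),
  now_tomorrow = c(participant_id = "character", trial = "numeric",
                   N_R = "numeric", R_i = "numeric", N_E = "numeric",
                   E_j = "numeric", chose_tomorrow = "numeric"),
  summaries = c(id = "character", k_R = "numeric", k_E = "numeric",
                procrastination_level = "numeric", form_delay = "numeric",
                age = "numeric", gender = "numeric")
)

validate_table <- function(df, schema_name, path = "<data>",
                           optional = character(0)) {
  schema <- TABLE_SCHEMAS[[schema_name]]
  required <- setdiff(names(schema), optional)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_config(path, ": missing column(s): ", paste(missing, collapse = ", "))
  }
  problems <- character(0)
  for (col in intersect(names(schema), names(df))) {
    if (schema[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "" & df[[col]] != "NA")
      if (length(bad)) {
        problems <- c(problems, sprintf("column '%s': non-numeric value at row(s) %s",
                                        col, paste(utils::head(bad, 5), collapse = ", ")))
      }
      df[[col]] <- v
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  if (length(problems)) {
    stop_config(path, ": ", paste(problems, collapse = "; "))
  }
  df
}

read_table_checked <- function(path, schema_name, optional = character(0)) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, schema_name, path = path, optional = optional)
}

#' Read a monetary-equivalence ratings table
#'
#' CSV with columns `participant_id`, `item_id`, `category`,
#' `subcategory`, `q1`, `q5`. Non-positive rating quantities are
#' rejected with their row numbers.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_ratings <- function(path) {
  df <- read_table_checked(path, "ratings")
  bad <- which(!is.finite(df$q1) | !is.finite(df$q5) | df$q1 <= 0 | df$q5 <= 0)
  if (length(bad)) {
    stop_config(path, ": non-positive rating quantity at row(s) ",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  df
}

#' Read an intertemporal choice-trial table
#'
#' @param path CSV file path.
#' @param delays admissible delay set; trials with delays outside it are
#'   rejected.
#' @return validated data frame (the `chose_later` column is optional,
#'   for not-yet-simulated choice sets).
#' @export
read_choice_trials <- function(path, delays = DEFAULT_DELAY_SET) {
  df <- read_table_checked(path, "choice_trials", optional = "chose_later")
  bad <- which(!(df$delay_sooner %in% delays) | !(df$delay_later %in% delays))
  if (length(bad)) {
    stop_config(path, ": delay outside the admissible set at row(s) ",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  df
}

#' Read a now/tomorrow trial table
#' @param path CSV file path.
#' @return validated data frame (`chose_tomorrow` optional).
#' @export
read_now_tomorrow_trials <- function(path) {
  read_table_checked(path, "now_tomorrow", optional = "chose_tomorrow")
}

#' Read a participant summary table
#'
#' @param path CSV file path.
#' @param deadline upper bound (days) for `form_delay`; values outside
#'   `[0, deadline]` are a validation error (never-returners are coded
#'   as empty/NA, not as out-of-range values).
#' @return validated data frame.
#' @export
read_participant_summaries <- function(path, deadline = 30) {
  df <- read_table_checked(path, "summaries",
                           optional = c("form_delay", "procrastination_level"))
  if ("form_delay" %in% names(df)) {
    bad <- which(!is.na(df$form_delay) &
                   (df$form_delay < 0 | df$form_delay > deadline))
    if (length(bad)) {
      stop_config(path, ": form_delay outside [0, ", deadline, "] at row(s) ",
                  paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  df
}

#' Write a data frame as CSV
#' @param df data frame.
#' @param path output path (parent directory is created).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# --- run configuration ------------------------------------------------------

RUN_CONFIG_DEFAULTS <- list(
  seed = 1,
  outdir = "procrastinatr-out",
  n_participants = 43,
  n_trials_per_category = 60,
  n_now_tomorrow_trials = 150,
  deadline = 30,
  families = c("hyperbolic_specific", "hyperbolic_shared",
               "present_bias", "quasi_hyperbolic"),
  n_restarts = 10,
  home_theta = 0.5,
  grid_n_samples = 10000,
  unit_value_method = "quantity",   # or "euro"
  value_normalization = "max_abs",  # or "zscore", "none"
  log_rates_in_regression = TRUE,
  ratings = NULL, trials = NULL, now_tomorrow = NULL, summaries = NULL
)

#' Read and validate a YAML run configuration
#'
#' Unknown keys are an error (naming the key); any referenced input path
#' must exist. Missing keys take the documented defaults, including the
#' flags selecting the alternative conventions (unit-value averaging,
#' value normalization, log-scale regression).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- RUN_CONFIG_DEFAULTS
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: ", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(RUN_CONFIG_DEFAULTS))
    if (length(unknown)) {
      stop_config("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  for (key in c("ratings", "trials", "now_tomorrow", "summaries")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop_config("config key '", key, "' references a missing file: ", cfg[[key]])
    }
  }
  if (!cfg$unit_value_method %in% c("quantity", "euro")) {
    stop_config("config key 'unit_value_method' must be 'quantity' or 'euro'")
  }
  if (!cfg$value_normalization %in% c("max_abs", "zscore", "none")) {
    stop_config("config key 'value_normalization' must be 'max_abs', 'zscore' or 'none'")
  }
  cfg
}

#' Write a run manifest
#'
#' JSON record of the configuration (with an md5 hash), the seed and the
#' package version, so every output is regenerable.
#'
#' @param outdir output directory.
#' @param config configuration list.
#' @param seed integer seed used for the run.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(outdir, config, seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(yaml::as.yaml(config), tmp)
  manifest <- list(
    package = "procrastinatr",
    version = as.character(utils::packageVersion("procrastinatr")),
    seed = seed,
    config = config,
    config_md5 = unname(tools::md5sum(tmp))
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
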