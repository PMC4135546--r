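#' Write cohort trial records to a tidy CSV
#'
#' Long format, one row per trial: `run`, `phase`, `session`, `trial`,
#' `outcome`, `latency`, `n_presses`, `anticipatory_presses_session` (the
#' session's anticipatory-press count, repeated on each of its trials).
#'
#' @param runs A list of `avoid_run` objects, a single run, or an
#'   `avoid_cohort`.
#' @param path Output file path.
#' @return The written data frame, invisibly.
#' @export
write_trials_csv <- function(runs, path) {
  df <- trials_long(runs)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(df)
}

trials_long <- function(runs) {
  runs <- as_run_list(runs)
  do.call(rbind, lapply(runs, function(r) {
    tr <- r$trials
    data.frame(run = tr$run, phase = tr$phase, session = tr$session,
               trial = tr$trial, outcome = tr$outcome, latency = tr$latency,
               n_presses = tr$n_presses,
               anticipatory_presses_session = r$anticipatory[tr$session],
               stringsAsFactors = FALSE)
  }))
}

#' Read trial records written by [write_trials_csv()]
#'
#' @param path CSV file path.
#' @return Data frame with the columns described in [write_trials_csv()].
#' @export
read_trials_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a cohort summary to JSON
#'
#' The summary echoes the fully resolved model parameters, task
#' configuration, seeds and package version, so the file alone suffices to
#' re-launch the identical experiment.
#'
#' @param cohort An `avoid_cohort` (see [run_cohort()]).
#' @param path Output file path.
#' @return The summary list, invisibly.
#' @export
write_summary_json <- function(cohort, path) {
  s <- cohort_summary_list(cohort)
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(s)
}

cohort_summary_list <- function(cohort) {
  list(
    label = cohort$label,
    n_runs = cohort$n_runs,
    base_seed = cohort$base_seed,
    seeds = cohort$seeds,
    software_version = as.character(utils::packageVersion("avoidrl")),
    params = unclass(cohort$params),
    config = unclass(cohort$config),
    percent_avoidance = list(mean = unname(cohort$pct_avoid_mean),
                             sem = unname(cohort$pct_avoid_sem)),
    latency = list(mean = unname(cohort$latency_mean),
                   sem = unname(cohort$latency_sem)),
    warmup = if (!is.null(cohort$warmup)) {
      list(sessions = cohort$warmup_sessions, mean = cohort$warmup$mean,
           sem = cohort$warmup$sem, per_run = cohort$warmup$per_run)
    },
    block_trial_curves = cohort$block_curves
  )
}

config_defaults <- function() {
  list(model = unclass(strain_preset("SD")$params),
       task = unclass(task_config()),
       cohort = list(n_runs = 10L, base_seed = 1L))
}

#' Load an experiment configuration file
#'
#' YAML with up to four sections: `model` (any [model_params()] field, or
#' `strain: SD|WKY` to start from a preset), `task` (any [task_config()]
#' field), `cohort` (`n_runs`, `base_seed`), and `condition`
#' (`type`/`value` for [make_condition()]). Unknown keys are rejected; every
#' omitted value keeps the standard-condition default (SD preset, 54-timestep
#' trials, 18000-timestep inter-session interval).
#'
#' @param path Path to the YAML file; an empty or absent-body file yields
#'   the defaults.
#' @param overrides Optional named list (`model`, `task`, `cohort` sections)
#'   merged over the file values, e.g. from command-line flags.
#' @return List with resolved `params`, `config`, `n_runs`, `base_seed`,
#'   `label`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  raw <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  } else list()
  bad <- setdiff(names(raw), c("model", "task", "cohort", "condition"))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (sec in names(overrides)) {
    raw[[sec]] <- utils::modifyList(as.list(raw[[sec]]),
                                    overrides[[sec]])
  }

  model_raw <- as.list(raw$model)
  strain <- model_raw$strain
  model_raw$strain <- NULL
  base_params <- if (!is.null(strain)) strain_preset(strain)$params
                 else strain_preset("SD")$params
  check_keys(model_raw, names(unclass(model_params())), "model")
  params <- merge_section(unclass(base_params), model_raw, "model")
  params <- do.call(model_params, params)

  task_raw <- as.list(raw$task)
  check_keys(task_raw, names(unclass(task_config())), "task")
  config <- merge_section(unclass(task_config()), task_raw, "task")
  config <- do.call(task_config, config)

  cohort_raw <- as.list(raw$cohort)
  check_keys(cohort_raw, c("n_runs", "base_seed"), "cohort")
  cohort <- utils::modifyList(list(n_runs = 10L, base_seed = 1L), cohort_raw)
  for (k in c("n_runs", "base_seed")) {
    if (!is.numeric(cohort[[k]]) || length(cohort[[k]]) != 1L) {
      stop("cohort key '", k, "' must be a single number", call. = FALSE)
    }
  }

  label <- if (!is.null(strain)) strain else "SD"
  if (!is.null(raw$condition)) {
    cnd <- as.list(raw$condition)
    check_keys(cnd, c("type", "value"), "condition")
    mc <- make_condition(params, config, type = cnd$type, value = cnd$value)
    params <- mc$params; config <- mc$config
    label <- paste(label, mc$label)
  }
  list(params = params, config = config,
       n_runs = as.integer(cohort$n_runs),
       base_seed = as.integer(cohort$base_seed), label = label)
}

check_keys <- function(given, allowed, section) {
  bad <- setdiff(names(given), allowed)
  if (length(bad)) {
    stop("unknown key(s) in config section '", section, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(given)
}

merge_section <- function(defaults, given, section) {
  for (k in names(given)) {
    val <- given[[k]]
    if (is.logical(defaults[[k]])) {
      if (!is.logical(val)) stop("config key '", k, "' must be logical",
                                 call. = FALSE)
    } else if (!is.numeric(val) || length(val) != 1L || is.na(val)) {
      stop("config key '", k, "' must be a single number", call. = FALSE)
    }
    defaults[[k]] <- val
  }
  defaults
}
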