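#' Strain parameter presets
#'
#' `"SD"` (Sprague-Dawley, outbred control): `alpha = 0.05`,
#' `epsilon = 0.005`, `temperature = 1.0`, `persev = 0.25`.
#' `"WKY"` (Wistar Kyoto, behaviorally inhibited): `alpha = 0.005`,
#' `temperature = 0.25`, `persev = 0`; every parameter not listed is
#' inherited unchanged from the SD preset.
#'
#' @param name `"SD"` or `"WKY"`.
#' @return An object of class `strain_preset`: list with `name` and a
#'   [model_params()] object `params`.
#' @examples
#' strain_preset("WKY")$params$temperature
#' @export
strain_preset <- function(name) {
  if (!name %in% c("SD", "WKY")) {
    stop("unknown strain: ", name, " (expected \"SD\" or \"WKY\")",
         call. = FALSE)
  }
  params <- switch(name,
    SD  = model_params(),
    WKY = model_params(alpha = 0.005, temperature = 0.25, persev = 0))
  structure(list(name = name, params = params), class = "strain_preset")
}

#' Run a cohort of replicate simulated subjects
#'
#' Executes [run_experiment()] with seeds `base_seed`, `base_seed + 1`, ...,
#' `base_seed + n_runs - 1` and aggregates the behavioral metrics across
#' runs. Comparisons between conditions should reuse the same `base_seed`
#' (paired design), which the experiment helpers here do by default.
#'
#' @param preset A `strain_preset`, [model_params()] object, or plain list of
#'   parameter values.
#' @param config A [task_config()].
#' @param n_runs Number of replicate runs (default 10).
#' @param base_seed First seed of the cohort.
#' @param label Condition label stored in the summary.
#' @param warmup_sessions Session window for the warm-up difference score
#'   (default 10:12, the last acquisition block).
#' @param engine Simulation engine, see [run_experiment()].
#' @param keep_runs Keep the raw `avoid_run` objects in the result?
#' @return An object of class `avoid_cohort`: per-session mean/SEM of
#'   percent avoidance and latency across runs, session-block trial curves,
#'   the warm-up score, and (optionally) the raw runs.
#' @export
run_cohort <- function(preset, config = task_config(), n_runs = 10L,
                       base_seed = 1L, label = NULL,
                       warmup_sessions = 10:12,
                       engine = c("compiled", "reference"),
                       keep_runs = TRUE) {
  stopifnot(n_runs >= 1L)
  engine <- match.arg(engine)
  params <- as_params(preset)
  if (is.null(label)) {
    label <- if (inherits(preset, "strain_preset")) preset$name else "custom"
  }
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  runs <- lapply(seq_len(n_runs), function(j) {
    r <- run_experiment(params, config, seed = seeds[j], engine = engine)
    r$run <- j
    r
  })
  summarize_cohort(runs, label = label, params = params, config = config,
                   base_seed = as.integer(base_seed),
                   warmup_sessions = warmup_sessions, keep_runs = keep_runs)
}

summarize_cohort <- function(runs, label = "cohort", params = NULL,
                             config = NULL, base_seed = NA_integer_,
                             warmup_sessions = 10:12, keep_runs = TRUE) {
  runs <- as_run_list(runs)
  n_runs <- length(runs)
  n_sessions <- length(unique(runs[[1]]$trials$session))
  as_run_matrix <- function(x) {
    if (n_sessions == 1L) matrix(x, ncol = 1L) else t(x)
  }
  pct <- as_run_matrix(vapply(runs, percent_avoidance_by_session,
                              numeric(n_sessions)))
  lat <- as_run_matrix(vapply(runs, latency_by_session, numeric(n_sessions)))
  warm <- if (all(warmup_sessions %in% runs[[1]]$trials$session)) {
    warmup_score(runs, sessions = warmup_sessions)
  } else NULL
  blocks <- if (n_sessions >= 3L) block_trial_curve(runs, 3L) else NULL
  structure(list(
    label = label, n_runs = n_runs, base_seed = base_seed,
    seeds = vapply(runs, `[[`, 0L, "seed"),
    params = params, config = config,
    pct_avoid = pct,
    pct_avoid_mean = colMeans(pct),
    pct_avoid_sem = apply(pct, 2, sem),
    latency = lat,
    latency_mean = colMeans(lat),
    latency_sem = apply(lat, 2, sem),
    block_curves = blocks,
    warmup = warm,
    warmup_sessions = warmup_sessions,
    runs = if (keep_runs) runs else NULL
  ), class = "avoid_cohort")
}

#' @export
print.avoid_cohort <- function(x, ...) {
  cat(sprintf("<avoid_cohort> %s: %d runs x %d sessions\n",
              x$label, x$n_runs, length(x$pct_avoid_mean)))
  cat(sprintf("  final acquisition %% avoid: %.1f (SEM %.2f)\n",
              x$pct_avoid_mean[x$config$n_acq_sessions],
              x$pct_avoid_sem[x$config$n_acq_sessions]))
  if (!is.null(x$warmup)) {
    cat(sprintf("  warm-up score (sessions %s): %.3f (SEM %.3f)\n",
                paste(range(x$warmup_sessions), collapse = "-"),
                x$warmup$mean, x$warmup$sem))
  }
  invisible(x)
}

#' Build an experimental condition from the standard one
#'
#' Applies one of the published manipulations to a parameter/config pair:
#' \describe{
#'   \item{`"shock_intensity"`}{sets `r_shock` (e.g. -8 for the doubled
#'     intensity; the critic clipping bound scales with it).}
#'   \item{`"isi"`}{sets `warning_len` (timesteps; 1 for the 10-s warning
#'     signal).}
#'   \item{`"intersession"`}{sets `intersession_len`; accepts timesteps, raw
#'     seconds via [interval_to_timesteps()], or a label such as `"30m"`,
#'     `"48h"`, `"30d"`, `"contin"`. Continuous sessions (length 0) also drop
#'     the pre-session period, as in the continuous-housing condition.}
#'   \item{`"housing"`}{toggles `round_the_clock`.}
#' }
#'
#' @param params A [model_params()] object (or preset).
#' @param config A [task_config()].
#' @param type Manipulation name.
#' @param value Manipulation value (see above).
#' @return `list(params =, config =, label =)`.
#' @export
make_condition <- function(params, config = task_config(),
                           type = c("shock_intensity", "isi", "intersession",
                                    "housing"),
                           value) {
  type <- match.arg(type)
  params <- as_params(params)
  label <- paste0(type, "=", value)
  switch(type,
    shock_intensity = {
      stopifnot(is.numeric(value), value < params$r_press)
      params$r_shock <- value
      validate_params(params)
    },
    isi = {
      stopifnot(is.numeric(value), value >= 1)
      config$warning_len <- as.integer(value)
    },
    intersession = {
      len <- interval_to_timesteps(value)
      stopifnot(len >= 0)
      config$intersession_len <- as.integer(len)
      if (len == 0L) config$pre_len <- 0L  # continuous sessions: no pre period
    },
    housing = {
      stopifnot(is.logical(value))
      config$round_the_clock <- value
    })
  list(params = params, config = config, label = label)
}

#' Convert an inter-session interval to timesteps
#'
#' Numeric input is taken as seconds of simulated time and converted at 10 s
#' per timestep. Labels combine a number with `m` (minutes), `h` (hours) or
#' `d` (days), e.g. `"30m"`, `"6h"`, `"30d"`; `"contin"` means 0. The
#' `"48h"` label maps to the standard 18000-timestep preset rather than the
#' literal conversion.
#'
#' @param x Numeric seconds, numeric timesteps via `"steps:<n>"`, or a label.
#' @return Integer number of timesteps.
#' @export
interval_to_timesteps <- function(x) {
  if (is.numeric(x)) return(as.integer(round(x / 10)))
  x <- trimws(x)
  if (x == "contin") return(0L)
  if (x == "48h") return(18000L)  # the published standard condition
  if (grepl("^steps:[0-9]+$", x)) return(as.integer(sub("^steps:", "", x)))
  m <- regmatches(x, regexec("^([0-9.]+)(m|h|d)$", x))[[1]]
  if (length(m) == 3L) {
    secs <- as.numeric(m[2]) * switch(m[3], m = 60, h = 3600, d = 86400)
    return(as.integer(round(secs / 10)))
  }
  if (grepl("^[0-9]+$", x)) return(as.integer(round(as.numeric(x) / 10)))
  stop("cannot parse inter-session interval: ", x, call. = FALSE)
}

#' Sweep one model parameter across a cohort battery
#'
#' Runs one cohort per value of the swept parameter, holding everything else
#' (including seeds) at the base preset so comparisons are paired.
#'
#' @param base A `strain_preset` or [model_params()] object.
#' @param axis One of `"alpha"`, `"epsilon"`, `"temperature"`, `"persev"`.
#' @param values Numeric values to sweep.
#' @inheritParams run_cohort
#' @return Named list of `avoid_cohort` objects (one per value).
#' @export
parameter_sweep <- function(base, axis, values, config = task_config(),
                            n_runs = 10L, base_seed = 1L,
                            engine = c("compiled", "reference")) {
  stopifnot(axis %in% c("alpha", "epsilon", "temperature", "persev"),
            length(values) >= 1L, all(is.finite(values)))
  engine <- match.arg(engine)
  params <- as_params(base)
  out <- lapply(values, function(val) {
    p <- params
    p[[axis]] <- val
    validate_params(p)
    run_cohort(p, config, n_runs = n_runs, base_seed = base_seed,
               label = paste0(axis, "=", val), engine = engine)
  })
  names(out) <- paste0(axis, "=", values)
  out
}
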