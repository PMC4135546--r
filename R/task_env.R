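#' Task schedule configuration
#'
#' Describes the discriminated lever-press avoidance schedule. One timestep
#' represents about 10 s of simulated time; the default trial is 54 timesteps
#' (6 warning + 30 shock + 18 ITI), sessions hold 20 trials preceded by a
#' 6-timestep stimulus-free pre-period, and consecutive sessions are
#' separated by an 18000-timestep home-cage period (the "standard" 48-h
#' alternating-day schedule).
#'
#' @param warning_len Timesteps of the warning-only period (default 6; the
#'   short-ISI manipulation uses 1).
#' @param shock_len Timesteps of the shock period (default 30).
#' @param iti_len Timesteps of the signaled inter-trial interval (default 18).
#' @param pre_len Stimulus-free timesteps at session start (default 6; 0 for
#'   continuous sessions).
#' @param trials_per_session Trials per session (default 20).
#' @param n_acq_sessions Number of acquisition sessions (default 12).
#' @param n_ext_sessions Number of extinction sessions (default 12).
#' @param intersession_len Home-cage timesteps between consecutive sessions
#'   (default 18000; 0 for continuous sessions).
#' @param round_the_clock If `TRUE`, the context input stays on the
#'   experimental chamber during inter-session periods (round-the-clock
#'   housing).
#' @param lever_available_between If `TRUE`, lever-press remains selectable
#'   during inter-session periods (disabled by default).
#' @param timestep_seconds Seconds represented by one timestep (fixed 10;
#'   used for interval conversion only).
#' @return An object of class `avoid_task`.
#' @export
task_config <- function(warning_len = 6L, shock_len = 30L, iti_len = 18L,
                        pre_len = 6L, trials_per_session = 20L,
                        n_acq_sessions = 12L, n_ext_sessions = 12L,
                        intersession_len = 18000L, round_the_clock = FALSE,
                        lever_available_between = FALSE,
                        timestep_seconds = 10) {
  cfg <- list(warning_len = as.integer(warning_len),
              shock_len = as.integer(shock_len),
              iti_len = as.integer(iti_len),
              pre_len = as.integer(pre_len),
              trials_per_session = as.integer(trials_per_session),
              n_acq_sessions = as.integer(n_acq_sessions),
              n_ext_sessions = as.integer(n_ext_sessions),
              intersession_len = as.integer(intersession_len),
              round_the_clock = isTRUE(round_the_clock),
              lever_available_between = isTRUE(lever_available_between),
              timestep_seconds = timestep_seconds)
  with(cfg, stopifnot(warning_len >= 1L, shock_len >= 0L, iti_len >= 0L,
                      pre_len >= 0L, trials_per_session >= 0L,
                      n_acq_sessions >= 0L, n_ext_sessions >= 0L,
                      intersession_len >= 0L))
  structure(cfg, class = "avoid_task")
}

#' @export
print.avoid_task <- function(x, ...) {
  cat("<avoid_task>\n")
  cat(sprintf("  trial: %d warning + %d shock + %d ITI timesteps (max %d)\n",
              x$warning_len, x$shock_len, x$iti_len, trial_len_max(x)))
  cat(sprintf("  sessions: %d acquisition + %d extinction, %d trials each, pre=%d\n",
              x$n_acq_sessions, x$n_ext_sessions, x$trials_per_session,
              x$pre_len))
  cat(sprintf("  intersession: %d timesteps%s%s\n", x$intersession_len,
              if (x$round_the_clock) ", round-the-clock housing" else "",
              if (x$lever_available_between) ", lever available" else ""))
  invisible(x)
}

trial_len_max <- function(config) {
  config$warning_len + config$shock_len + config$iti_len
}

#' Encode task-phase inputs
#'
#' Maps a task phase to the 5-unit binary input vector
#' `(W, S, U, ctx_chamber, ctx_home)`. The shock unit is only active during
#' acquisition shock periods; extinction reuses the warning encoding with
#' `U = 0`. Inter-session periods present the home-cage context unless
#' round-the-clock housing is configured.
#'
#' @param phase_tag One of `"pre"`, `"warning"`, `"shock"`, `"iti"`,
#'   `"intersession"`.
#' @param config A [task_config()].
#' @return Named binary vector of length 5.
#' @export
encode_inputs <- function(phase_tag, config = task_config()) {
  v <- switch(phase_tag,
    pre          = c(0, 0, 0, 1, 0),
    warning      = c(1, 0, 0, 1, 0),
    shock        = c(1, 0, 1, 1, 0),
    iti          = c(0, 1, 0, 1, 0),
    intersession = if (config$round_the_clock) c(0, 0, 0, 1, 0)
                   else c(0, 0, 0, 0, 1),
    stop("unknown phase tag: ", phase_tag, call. = FALSE))
  stats::setNames(v, INPUT_NAMES)
}

shock_period_inputs <- function(phase, config) {
  if (phase == "acquisition") encode_inputs("shock", config)
  else encode_inputs("warning", config)  # extinction: W stays on, U withheld
}

#' Run one avoidance trial (reference engine)
#'
#' Executes the within-trial timeline: `warning_len` warning timesteps, then
#' `shock_len` shock-period timesteps (shock delivered in acquisition only),
#' then `iti_len` ITI timesteps. A lever-press during the warning or shock
#' period truncates the remainder of that period and jumps to the ITI at the
#' next timestep; ITI presses have no scheduling effect but incur the press
#' cost. Every timestep runs a full learning step.
#'
#' @param agent An [agent_state()].
#' @param params A [model_params()] object.
#' @param config A [task_config()].
#' @param phase `"acquisition"` or `"extinction"`.
#' @param policy Optional scripted policy `function(step, segment)` returning
#'   an action index; bypasses softmax selection (used for environment
#'   oracles). `NULL` (default) samples from the softmax.
#' @param next_inputs Input vector presented at the timestep following the
#'   trial's last ITI timestep (the next trial's warning inputs, or the
#'   inter-session inputs after the session's last trial).
#' @param debug If `TRUE`, attach the per-timestep input matrix, actions and
#'   reinforcements to the returned record.
#' @return `list(agent =, record =)` where `record` has `outcome`
#'   (`"avoid"`, `"escape"` or `"none"`), `latency` (timesteps since warning
#'   onset of the first press; trial maximum if none), `n_presses`,
#'   `press_times` and `trial_length`.
#' @export
run_trial <- function(agent, params, config, phase = "acquisition",
                      policy = NULL, next_inputs = encode_inputs("intersession", config),
                      debug = FALSE) {
  check_agent_dims(agent, params)
  allowed <- seq_len(params$n_actions)
  seg <- "warning"; seg_step <- 0L
  t_in <- 0L
  first_press <- NA_integer_; first_seg <- NA_character_
  press_times <- integer(0)
  dbg <- if (debug) list(inputs = NULL, actions = integer(0), R = numeric(0),
                         segs = character(0)) else NULL

  seg_inputs <- function(seg) {
    switch(seg,
           warning = encode_inputs("warning", config),
           shock   = shock_period_inputs(phase, config),
           iti     = encode_inputs("iti", config))
  }

  repeat {
    I_cur <- seg_inputs(seg)
    action <- if (!is.null(policy)) policy(t_in, seg) else NULL
    # advance the state machine assuming the chosen action
    if (is.null(action)) {
      M <- action_values(agent, I_cur, params)
      action <- select_action(M, params, allowed)
    }
    pressed <- action == LEVER_ACTION

    if (pressed && seg %in% c("warning", "shock")) {
      nseg <- "iti"; nstep <- 0L
    } else {
      nseg <- seg; nstep <- seg_step + 1L
    }
    # skip zero-length or exhausted segments
    while (nseg != "done" &&
           nstep >= switch(nseg, warning = config$warning_len,
                           shock = config$shock_len, iti = config$iti_len)) {
      nstep <- 0L
      nseg <- switch(nseg, warning = "shock", shock = "iti", iti = "done")
    }
    done <- identical(nseg, "done")
    I_next <- if (done) next_inputs else seg_inputs(nseg)
    shock_next <- !done && nseg == "shock" && phase == "acquisition"

    res <- learn_step(agent, params, I_cur, I_next, shock_next, action)
    agent <- res$state

    if (pressed) {
      press_times <- c(press_times, t_in)
      if (is.na(first_press)) { first_press <- t_in; first_seg <- seg }
    }
    if (debug) {
      dbg$inputs <- rbind(dbg$inputs, I_cur)
      dbg$actions <- c(dbg$actions, action)
      dbg$R <- c(dbg$R, res$R)
      dbg$segs <- c(dbg$segs, seg)
    }
    t_in <- t_in + 1L
    if (done) break
    seg <- nseg; seg_step <- nstep
  }

  outcome <- if (is.na(first_press)) "none"
             else switch(first_seg, warning = "avoid", shock = "escape",
                         iti = "none")
  record <- list(outcome = outcome,
                 latency = if (is.na(first_press)) trial_len_max(config)
                           else first_press,
                 n_presses = length(press_times),
                 press_times = press_times,
                 trial_length = t_in)
  if (debug) record$debug <- dbg
  list(agent = agent, record = record)
}

# wraps agent_step so scripted actions skip RNG consumption
learn_step <- function(agent, params, I_cur, I_next, shock_next,
                       action = NULL) {
  agent_step(agent, params, I_cur, I_next, shock_next,
             allowed = seq_len(params$n_actions), action = action)
}

#' Run one session (reference engine)
#'
#' A session is `pre_len` stimulus-free timesteps in the chamber (presses
#' counted as anticipatory responses) followed by `trials_per_session`
#' trials.
#'
#' @inheritParams run_trial
#' @param next_inputs Inputs following the session's final timestep
#'   (inter-session inputs under the standard schedule).
#' @return `list(agent =, record =)`; `record` holds `phase`, a `trials`
#'   list of trial records and the `anticipatory_presses` count.
#' @export
run_session <- function(agent, params, config, phase = "acquisition",
                        policy = NULL,
                        next_inputs = encode_inputs("intersession", config),
                        debug = FALSE) {
  n_trials <- config$trials_per_session
  first_trial_inputs <- encode_inputs("warning", config)
  after_pre <- if (n_trials > 0L) first_trial_inputs else next_inputs

  anticipatory <- 0L
  pre_inputs <- encode_inputs("pre", config)
  for (k in seq_len(config$pre_len)) {
    I_next <- if (k < config$pre_len) pre_inputs else after_pre
    action <- if (!is.null(policy)) policy(k - 1L, "pre") else NULL
    res <- learn_step(agent, params, pre_inputs, I_next, FALSE, action)
    agent <- res$state
    if (res$pressed) anticipatory <- anticipatory + 1L
  }

  trials <- vector("list", n_trials)
  for (j in seq_len(n_trials)) {
    nx <- if (j < n_trials) first_trial_inputs else next_inputs
    out <- run_trial(agent, params, config, phase, policy, nx, debug)
    agent <- out$agent
    trials[[j]] <- out$record
  }
  list(agent = agent,
       record = list(phase = phase, trials = trials,
                     anticipatory_presses = anticipatory))
}

#' Run an inter-session (home-cage) period (reference engine)
#'
#' `intersession_len` timesteps with the home-cage context input (chamber
#' under round-the-clock housing), no task stimuli, and lever-press removed
#' from the allowed action set unless `lever_available_between`. No shock or
#' press cost occurs while the lever is disabled, so `R = 0`; learning steps
#' still run, so value expectations relax and perseveration traces turn over.
#'
#' @inheritParams run_session
#' @param next_inputs Inputs following the period's final timestep (the next
#'   session's pre-period inputs under the standard schedule).
#' @param debug If `TRUE`, also return the executed action log.
#' @return The updated agent (or `list(agent =, actions =)` when `debug`).
#' @export
run_intersession <- function(agent, params, config,
                             next_inputs = encode_inputs("pre", config),
                             debug = FALSE) {
  I_cur <- encode_inputs("intersession", config)
  allowed <- if (config$lever_available_between) seq_len(params$n_actions)
             else seq_len(params$n_actions)[-LEVER_ACTION]
  n <- config$intersession_len
  actions <- if (debug) integer(n) else NULL
  for (k in seq_len(n)) {
    I_next <- if (k < n) I_cur else next_inputs
    res <- agent_step(agent, params, I_cur, I_next, FALSE, allowed)
    agent <- res$state
    if (debug) actions[k] <- res$action
  }
  if (debug) list(agent = agent, actions = actions) else agent
}

session_first_inputs <- function(config) {
  if (config$pre_len > 0L) encode_inputs("pre", config)
  else if (config$trials_per_session > 0L) encode_inputs("warning", config)
  else encode_inputs("intersession", config)
}

#' Run a full simulated subject
#'
#' Starts from a fresh [agent_state()] and alternates sessions and
#' inter-session periods: `n_acq_sessions` acquisition sessions, then
#' `n_ext_sessions` extinction sessions (identical except shock is never
#' delivered), with an inter-session period between every pair of
#' consecutive sessions including the acquisition-to-extinction boundary.
#' Deterministic given `seed`.
#'
#' The default `"compiled"` engine runs the whole event stream in C++ and is
#' arithmetic-identical to the pure-R `"reference"` engine (same random
#' stream, same accumulation order); the reference engine exists as a
#' readable executable description and for oracle tests.
#'
#' @inheritParams run_trial
#' @param seed Integer seed for the run (one independent stream per run).
#' @param engine `"compiled"` (default) or `"reference"`.
#' @param keep_state Keep the final agent state in the result?
#' @return An object of class `avoid_run`: list with `seed`, a tidy `trials`
#'   data frame (`session`, `trial`, `phase`, `outcome`, `latency`,
#'   `n_presses`, `trial_length`), per-session `anticipatory` counts, and
#'   optionally the final `state`.
#' @examples
#' cfg <- task_config(n_acq_sessions = 1, n_ext_sessions = 0,
#'                    trials_per_session = 2, intersession_len = 0)
#' run <- run_experiment(model_params(), cfg, seed = 1)
#' run$trials
#' @export
run_experiment <- function(params, config = task_config(), seed = 1L,
                           engine = c("compiled", "reference"),
                           keep_state = TRUE) {
  params <- as_params(params)
  engine <- match.arg(engine)
  set.seed(as.integer(seed))
  if (engine == "compiled") {
    raw <- engine_run(params, config, keep_state)
    trials <- data.frame(session = raw$session, trial = raw$trial,
                         phase = c("acquisition", "extinction")[raw$phase],
                         outcome = c("avoid", "escape", "none")[raw$outcome],
                         latency = raw$latency, n_presses = raw$n_presses,
                         trial_length = raw$trial_length,
                         stringsAsFactors = FALSE)
    state <- if (keep_state) {
      structure(list(m = raw$m, c = raw$c,
                     v = stats::setNames(raw$v, INPUT_NAMES),
                     v_prev = raw$v_prev), class = "avoid_agent")
    } else NULL
    res <- list(seed = as.integer(seed), trials = trials,
                anticipatory = raw$anticipatory, state = state,
                params = params, config = config)
    return(structure(res, class = "avoid_run"))
  }
  run_experiment_reference(params, config, keep_state = keep_state,
                           seed_used = as.integer(seed))
}

run_experiment_reference <- function(params, config, policy = NULL,
                                     keep_state = TRUE, seed_used = NA_integer_) {
  agent <- agent_state(params)
  n_sessions <- config$n_acq_sessions + config$n_ext_sessions
  inter_inputs <- encode_inputs("intersession", config)
  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    phase <- if (s <= config$n_acq_sessions) "acquisition" else "extinction"
    last_session <- s == n_sessions
    session_next <- if (last_session || config$intersession_len > 0L)
      inter_inputs else session_first_inputs(config)
    out <- run_session(agent, params, config, phase, policy, session_next)
    agent <- out$agent
    sessions[[s]] <- out$record
    if (!last_session && config$intersession_len > 0L) {
      agent <- run_intersession(agent, params, config,
                                next_inputs = session_first_inputs(config))
    }
  }
  trials <- do.call(rbind, lapply(seq_len(n_sessions), function(s) {
    tr <- sessions[[s]]$trials
    if (length(tr) == 0L) return(NULL)
    data.frame(session = s, trial = seq_along(tr),
               phase = sessions[[s]]$phase,
               outcome = vapply(tr, `[[`, "", "outcome"),
               latency = vapply(tr, `[[`, 0L, "latency"),
               n_presses = vapply(tr, `[[`, 0L, "n_presses"),
               trial_length = vapply(tr, `[[`, 0L, "trial_length"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(trials)) {
    trials <- data.frame(session = integer(0), trial = integer(0),
                         phase = character(0), outcome = character(0),
                         latency = integer(0), n_presses = integer(0),
                         trial_length = integer(0))
  }
  structure(list(seed = seed_used, trials = trials,
                 anticipatory = vapply(sessions, `[[`, 0L,
                                       "anticipatory_presses"),
                 state = if (keep_state) agent else NULL,
                 params = params, config = config),
            class = "avoid_run")
}

#' @export
print.avoid_run <- function(x, ...) {
  n_sess <- length(x$anticipatory)
  cat(sprintf("<avoid_run> seed=%s, %d sessions, %d trials\n",
              x$seed, n_sess, nrow(x$trials)))
  invisible(x)
}
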