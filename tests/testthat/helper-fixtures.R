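# Small configurations used across test files. Kept deliberately tiny so
# the reference (pure R) engine can be exercised directly.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_acq_sessions = 2L, n_ext_sessions = 1L, trials_per_session = 4L,
         intersession_len = 60L, pre_len = 3L),
    list(...))
  do.call(task_config, args)
}

# a policy stub that lever-presses at exactly one within-trial timestep
# (and never during the pre period)
press_at <- function(step_idx) {
  function(step, segment) {
    if (segment != "pre" && step == step_idx) 1L else 2L
  }
}

never_press <- function(step, segment) 2L
always_press <- function(step, segment) 1L

# hand-rolled avoid_run built from an outcome matrix (sessions x trials),
# entries in c("avoid", "escape", "none"); latency chosen consistently
fake_run <- function(outcomes, phase_split = nrow(outcomes),
                     config = task_config()) {
  n_s <- nrow(outcomes); n_t <- ncol(outcomes)
  lat <- ifelse(outcomes == "avoid", 2L,
                ifelse(outcomes == "escape", 10L, trial_len_max_test(config)))
  trials <- data.frame(
    session = rep(seq_len(n_s), each = n_t),
    trial = rep(seq_len(n_t), n_s),
    phase = rep(ifelse(seq_len(n_s) <= phase_split, "acquisition",
                       "extinction"), each = n_t),
    outcome = as.vector(t(outcomes)),
    latency = as.vector(t(lat)),
    n_presses = as.vector(t(outcomes != "none")) * 1L,
    trial_length = 54L,
    stringsAsFactors = FALSE)
  structure(list(seed = 0L, trials = trials,
                 anticipatory = integer(n_s), state = NULL,
                 params = model_params(), config = config),
            class = "avoid_run")
}

trial_len_max_test <- function(config) {
  config$warning_len + config$shock_len + config$iti_len
}
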