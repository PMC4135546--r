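test_that("phase input encodings are binary, one-hot in context, and shock implies warning", {
  cfg <- task_config()
  expect_equal(unname(encode_inputs("pre", cfg)), c(0, 0, 0, 1, 0))
  expect_equal(unname(encode_inputs("warning", cfg)), c(1, 0, 0, 1, 0))
  expect_equal(unname(encode_inputs("shock", cfg)), c(1, 0, 1, 1, 0))
  expect_equal(unname(encode_inputs("iti", cfg)), c(0, 1, 0, 1, 0))
  expect_equal(unname(encode_inputs("intersession", cfg)), c(0, 0, 0, 0, 1))
  rtc <- task_config(round_the_clock = TRUE)
  expect_equal(unname(encode_inputs("intersession", rtc)), c(0, 0, 0, 1, 0))
  for (tag in c("pre", "warning", "shock", "iti", "intersession")) {
    I <- encode_inputs(tag, cfg)
    expect_true(all(I %in% c(0, 1)))
    expect_equal(I[["ctx_chamber"]] + I[["ctx_home"]], 1)
    if (I[["U"]] == 1) expect_equal(I[["W"]], 1)
  }
  expect_error(encode_inputs("nonsense", cfg), "unknown phase")
})

test_that("scripted press times produce the hand-computed outcome, latency and length", {
  p <- model_params()
  cfg <- task_config()
  for (t_press in c(0:7, 20L, 34L, 35L, 36L, 45L, 53L)) {
    out <- run_trial(agent_state(p), p, cfg, "acquisition",
                     policy = press_at(t_press))
    rec <- out$record
    # independent scoring rules: warning = steps 0-5, shock = 6-35, ITI after
    if (t_press < 6) {
      expect_identical(rec$outcome, "avoid")
      expect_identical(rec$trial_length, t_press + 1L + 18L)
    } else if (t_press < 36) {
      expect_identical(rec$outcome, "escape")
      expect_identical(rec$trial_length, t_press + 1L + 18L)
    } else {
      expect_identical(rec$outcome, "none")
      expect_identical(rec$trial_length, 54L)
    }
    expect_identical(rec$latency, t_press)
    expect_identical(rec$press_times, t_press)
  }
  # never pressing: maximum latency, full-length trial
  out <- run_trial(agent_state(p), p, cfg, "acquisition", policy = never_press)
  expect_identical(out$record$outcome, "none")
  expect_identical(out$record$latency, 54L)
  expect_identical(out$record$trial_length, 54L)
  expect_identical(out$record$n_presses, 0L)
})

test_that("trials always end with exactly iti_len ITI timesteps", {
  p <- model_params()
  cfg <- task_config(iti_len = 7L)
  for (t_press in c(0, 3, 5, 6, 20, 35)) {
    out <- run_trial(agent_state(p), p, cfg, "acquisition",
                     policy = press_at(t_press), debug = TRUE)
    segs <- out$record$debug$segs
    expect_identical(sum(segs == "iti"), 7L)
    expect_identical(segs[(length(segs) - 6):length(segs)], rep("iti", 7))
  }
})

test_that("avoidance trials contain no shock input; extinction never presents shock", {
  p <- model_params()
  cfg <- task_config()
  out <- run_trial(agent_state(p), p, cfg, "acquisition",
                   policy = press_at(2L), debug = TRUE)
  expect_true(all(out$record$debug$inputs[, "U"] == 0))

  out_ext <- run_trial(agent_state(p), p, cfg, "extinction",
                       policy = never_press, debug = TRUE)
  expect_true(all(out_ext$record$debug$inputs[, "U"] == 0))
  # W stays on through the would-be shock period in extinction
  expect_identical(sum(out_ext$record$debug$inputs[, "W"]), 36)

  # acquisition without press: shock period delivers r_shock on each of the
  # 30 transitions into a shock timestep
  out_acq <- run_trial(agent_state(p), p, cfg, "acquisition",
                       policy = never_press, debug = TRUE)
  expect_identical(sum(out_acq$record$debug$R == p$r_shock), 30L)
})

test_that("sessions run the pre period, count anticipatory presses, and score trials", {
  p <- model_params()
  cfg <- tiny_config()
  out <- run_session(agent_state(p), p, cfg, "acquisition",
                     policy = always_press)
  rec <- out$record
  expect_length(rec$trials, 4L)
  expect_true(all(vapply(rec$trials, `[[`, "", "outcome") == "avoid"))
  expect_true(all(vapply(rec$trials, `[[`, 0L, "latency") == 0L))
  expect_identical(rec$anticipatory_presses, 3L)  # pressed on all 3 pre steps

  out2 <- run_session(agent_state(p), p, cfg, "acquisition",
                      policy = never_press)
  expect_identical(out2$record$anticipatory_presses, 0L)

  # degenerate: no trials
  cfg0 <- task_config(trials_per_session = 0L, pre_len = 6L)
  out0 <- run_session(agent_state(p), p, cfg0, "acquisition")
  expect_length(out0$record$trials, 0L)
  expect_true(out0$record$anticipatory_presses %in% 0:6)
})

test_that("intersession disables the lever and turns over traces", {
  p <- model_params()
  cfg <- task_config(intersession_len = 400L)
  st <- agent_state(p)
  st$c[, ] <- 1  # pretend everything was just executed
  set.seed(5)
  out <- run_intersession(st, p, cfg, debug = TRUE)
  expect_false(any(out$actions == 1L))
  # stale traces from before the period have fully decayed (0.95^400 < 1e-9);
  # only rows refreshed during the period retain trace
  stale <- setdiff(seq_len(p$n_actions), unique(out$actions))
  expect_true(all(out$agent$c[stale, ] < 1e-8))

  # zero-length period is a no-op
  cfg0 <- task_config(intersession_len = 0L)
  expect_identical(run_intersession(st, p, cfg0), st)

  # lever_available_between restores the full action set
  cfgL <- task_config(intersession_len = 400L, lever_available_between = TRUE)
  set.seed(5)
  outL <- run_intersession(st, p, cfgL, debug = TRUE)
  expect_true(any(outL$actions == 1L))
})

test_that("experiments have the right session structure and are seed-deterministic", {
  p <- model_params()
  cfg <- tiny_config()
  run <- run_experiment(p, cfg, seed = 9)
  expect_identical(length(run$anticipatory), 3L)
  expect_identical(nrow(run$trials), 12L)
  expect_identical(unique(run$trials$phase[run$trials$session <= 2]),
                   "acquisition")
  expect_identical(unique(run$trials$phase[run$trials$session == 3]),
                   "extinction")

  run2 <- run_experiment(p, cfg, seed = 9)
  expect_identical(run$trials, run2$trials)
  expect_identical(run$state, run2$state)
  run3 <- run_experiment(p, cfg, seed = 10)
  expect_false(identical(run$trials, run3$trials))

  # degenerate single-trial experiment
  cfg1 <- task_config(n_acq_sessions = 1L, n_ext_sessions = 0L,
                      trials_per_session = 1L, intersession_len = 0L)
  expect_identical(nrow(run_experiment(p, cfg1, seed = 1)$trials), 1L)
})

test_that("every trial outcome is exactly one of avoid/escape/none", {
  p <- model_params()
  cfg <- tiny_config()
  for (seed in 1:5) {
    run <- run_experiment(p, cfg, seed = seed)
    expect_true(all(run$trials$outcome %in% c("avoid", "escape", "none")))
    counts <- table(factor(run$trials$session, levels = 1:3))
    expect_true(all(counts == cfg$trials_per_session))
  }
})

test_that("compiled and reference engines produce identical trajectories", {
  p <- model_params()
  cfg <- tiny_config()
  a <- run_experiment(p, cfg, seed = 42, engine = "compiled")
  b <- run_experiment(p, cfg, seed = 42, engine = "reference")
  expect_identical(a$trials, b$trials)
  expect_identical(a$anticipatory, b$anticipatory)
  expect_identical(a$state$v, b$state$v)
  expect_identical(a$state$v_prev, b$state$v_prev)
  expect_identical(a$state$m, unname(b$state$m))
  expect_identical(a$state$c, unname(b$state$c))

  # also under the WKY preset, gated traces, and round-the-clock housing
  variants <- list(
    list(p = strain_preset("WKY")$params, cfg = tiny_config()),
    list(p = model_params(trace_gated = TRUE), cfg = tiny_config()),
    list(p = model_params(), cfg = tiny_config(round_the_clock = TRUE)),
    list(p = model_params(), cfg = tiny_config(intersession_len = 0L,
                                               pre_len = 0L)))
  for (vr in variants) {
    a <- run_experiment(vr$p, vr$cfg, seed = 7, engine = "compiled")
    b <- run_experiment(vr$p, vr$cfg, seed = 7, engine = "reference")
    expect_identical(a$trials, b$trials)
    expect_identical(a$state$m, unname(b$state$m))
    expect_identical(a$state$c, unname(b$state$c))
  }
})
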