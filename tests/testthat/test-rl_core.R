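test_that("parameter validation enforces the documented ranges", {
  expect_s3_class(model_params(), "avoid_params")
  expect_error(model_params(alpha = 0), "alpha")
  expect_error(model_params(temperature = -1), "temperature")
  expect_error(model_params(r_shock = -0.1), "r_shock < r_press")
  expect_error(model_params(r_press = 0.5), "r_shock < r_press")
  expect_error(model_params(n_actions = 1), "n_actions")
  expect_error(model_params(trace_decay = 1), "trace_decay")
})

test_that("action values combine weights and ungated perseveration traces", {
  p <- model_params(n_actions = 4L)
  st <- agent_state(p)

  # symmetric initialization: one active input, all m = m_init
  I <- encode_inputs("pre")
  expect_equal(action_values(st, I, p), rep(0.01, 4))

  # trace term is summed over all inputs regardless of which are active
  st$m[] <- 0
  st$c[2, ] <- 1
  expect_equal(action_values(st, I, p), c(0, 0.25 * 5, 0, 0))

  # P = 0 removes the trace term entirely, bitwise
  p0 <- model_params(n_actions = 4L, persev = 0)
  st_rand <- st
  set.seed(7)
  st_rand$c[] <- runif(20)
  st_rand$m[] <- runif(20)
  base <- action_values(st_rand, I, p0)
  st_zero_c <- st_rand; st_zero_c$c[] <- 0
  expect_identical(base, action_values(st_zero_c, I, p0))

  expect_error(action_values(agent_state(model_params(n_actions = 3L)), I, p),
               "dimensions")
})

test_that("softmax selection matches closed forms and normalizes", {
  p <- model_params()
  M <- c(1, 0)
  pr <- softmax_probs(M, 1.0, 1:2)
  expect_equal(pr[1], exp(1) / (exp(1) + 1), tolerance = 1e-12)
  pr_cold <- softmax_probs(M, 0.25, 1:2)
  expect_equal(pr_cold[1], exp(4) / (exp(4) + 1), tolerance = 1e-12)
  expect_gt(pr_cold[1], pr[1])  # lower T exploits harder

  # uniform when all values equal
  expect_equal(softmax_probs(rep(0.3, 100), 1, 1:100), rep(0.01, 100))

  # normalization within the allowed subset, for random values
  set.seed(1)
  for (k in 1:25) {
    M <- rnorm(50, sd = 10)
    allowed <- sort(sample(50, sample(2:50, 1)))
    pr <- softmax_probs(M, runif(1, 0.05, 5), allowed)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
  }

  # numerically stable for huge |M| / T
  pr <- softmax_probs(c(1e6, 1e6 - 1), 0.25, 1:2)
  expect_true(all(is.finite(pr)))
  expect_equal(sum(pr), 1, tolerance = 1e-12)

  expect_error(softmax_probs(M, 1, integer(0)), "empty")
})

test_that("lowering temperature raises the argmax selection probability", {
  set.seed(42)
  for (k in 1:20) {
    M <- rnorm(30)
    best <- which.max(M)
    hot <- softmax_probs(M, 2.0, 1:30)[best]
    cold <- softmax_probs(M, 0.5, 1:30)[best]
    expect_gt(cold, hot)
  }
})

test_that("select_action samples according to the softmax probabilities", {
  p <- model_params(temperature = 1)
  M <- c(2, 0, 0)
  # deterministic given the uniform draw
  expect_identical(select_action(M, p, 1:3, u = 1e-9), 1L)
  expect_identical(select_action(M, p, 1:3, u = 0.999999), 3L)
  # restricted allowed set never yields a disallowed action
  set.seed(3)
  picks <- replicate(200, select_action(M, p, allowed = 2:3))
  expect_true(all(picks %in% 2:3))
  # empirical frequency close to closed form (equal values -> 1/2)
  expect_equal(mean(picks == 2L), 0.5, tolerance = 0.1)
})

test_that("reinforcement rule: shock dominates, press costs, else nothing", {
  p <- model_params()
  expect_equal(reinforcement_signal(TRUE, FALSE, p), -0.2)
  expect_equal(reinforcement_signal(FALSE, TRUE, p), -4)
  expect_equal(reinforcement_signal(TRUE, TRUE, p), -4)  # costs never sum
  expect_equal(reinforcement_signal(FALSE, FALSE, p), 0)
})

test_that("state value is the inner product of critic weights and inputs", {
  p <- model_params()
  st <- agent_state(p)
  expect_equal(state_value(st, encode_inputs("shock")), 0)
  st$v <- c(-2, 0, 0, 0.5, 0)
  expect_equal(state_value(st, c(1, 0, 0, 1, 0)), -1.5)
  expect_equal(state_value(st, c(0, 0, 0, 0, 0)), 0)
})

test_that("prediction error follows the discounted TD rule", {
  p <- model_params()
  expect_equal(prediction_error(0, 0, 0, p), 0)
  expect_equal(prediction_error(-4, 0, -1, p), -3)
  expect_equal(prediction_error(0, -2, 0, p), -1.8)
})

test_that("critic update scales by alpha, gates on inputs, and clips", {
  p <- model_params()
  st <- agent_state(p)
  I <- c(1, 0, 0, 0, 0)
  st2 <- update_critic(st, -3, I, p)
  expect_equal(unname(st2$v), c(-0.15, 0, 0, 0, 0))

  # clipping at |r_shock|
  st$v[1] <- -3.9
  st3 <- update_critic(st, -0.2 / p$alpha, I, p)
  expect_equal(unname(st3$v[1]), -4)

  # PE = 0 leaves the state unchanged
  expect_equal(update_critic(st, 0, I, p)$v, st$v)
})

test_that("actor update changes only the executed row and floors at zero", {
  p <- model_params()
  st <- agent_state(p)
  I <- c(1, 0, 0, 0, 0)
  st2 <- update_actor(st, 5L, 2, I, p)
  expect_equal(unname(st2$m[5, 1]), 0.01 + 0.005 * (2 - 0.01))
  expect_equal(st2$m[-5, ], st$m[-5, ])     # other rows untouched
  expect_equal(st2$m[5, 2:5], st$m[5, 2:5]) # inactive inputs untouched

  st$m[7, 1] <- 0.001
  st3 <- update_actor(st, 7L, -4, I, p)
  expect_equal(unname(st3$m[7, 1]), 0)      # floored, never negative
})

test_that("trace update decays non-executed rows and refreshes the executed one", {
  p <- model_params(n_actions = 6L)
  st <- agent_state(p)
  st <- update_trace(st, 5L, p)
  expect_equal(unname(st$c[5, ]), rep(1, 5))
  expect_equal(unname(st$c[-5, ]), matrix(0, 5, 5))

  for (k in 1:14) st <- update_trace(st, 1L, p)
  expect_equal(unname(st$c[5, 1]), 0.95^14, tolerance = 1e-12)

  # gated variant refreshes only active columns
  pg <- model_params(n_actions = 6L, trace_gated = TRUE)
  stg <- agent_state(pg)
  stg <- update_trace(stg, 2L, pg, inputs = c(1, 0, 0, 1, 0))
  expect_equal(unname(stg$c[2, ]), c(1, 0, 0, 1, 0))
  expect_error(update_trace(stg, 2L, pg), "active inputs")
})

test_that("invariants hold after arbitrary update sequences", {
  p <- model_params()
  st <- agent_state(p)
  set.seed(11)
  phases <- c("pre", "warning", "shock", "iti", "intersession")
  for (k in 1:300) {
    I <- encode_inputs(sample(phases, 1))
    a <- sample(p$n_actions, 1)
    PE <- rnorm(1, sd = 5)
    st <- update_critic(st, PE, I, p)
    st <- update_actor(st, a, PE, I, p)
    st <- update_trace(st, a, p)
  }
  expect_true(all(st$m >= 0))
  expect_true(all(abs(st$v) <= abs(p$r_shock)))
  expect_true(all(st$c >= 0 & st$c <= 1))
})

test_that("zero reinforcement from zero-initialized weights produces no learning", {
  p <- model_params()
  st <- agent_state(p)
  st$m[] <- 0  # Delta-m = epsilon * (PE - m) decays any nonzero actor weight
  I <- encode_inputs("pre")
  for (k in 1:50) {
    res <- avoidrl:::agent_step(st, p, I, I, FALSE,
                                allowed = 1:p$n_actions, action = 3L)
    expect_identical(res$PE, 0)
    st_new <- res$state
    expect_identical(st_new$v, st$v)
    expect_identical(st_new$m, st$m)
    st <- st_new
  }
})
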