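#' Initialize an agent state
#'
#' Actor weights `m` start at `m_init`, perseveration traces `c` at 0, critic
#' weights `v` at 0, and the previous value prediction `v_prev` at 0.
#'
#' @param params An [model_params()] object.
#' @return An object of class `avoid_agent`: list with actor weight matrix
#'   `m` (`n_actions` x 5), trace matrix `c` (same shape), critic weight
#'   vector `v` (length 5) and scalar `v_prev`.
#' @export
agent_state <- function(params) {
  A <- params$n_actions
  structure(
    list(m = matrix(params$m_init, nrow = A, ncol = N_INPUTS,
                    dimnames = list(NULL, INPUT_NAMES)),
         c = matrix(0, nrow = A, ncol = N_INPUTS,
                    dimnames = list(NULL, INPUT_NAMES)),
         v = stats::setNames(numeric(N_INPUTS), INPUT_NAMES),
         v_prev = 0),
    class = "avoid_agent")
}

check_agent_dims <- function(state, params) {
  if (nrow(state$m) != params$n_actions || ncol(state$m) != N_INPUTS ||
      nrow(state$c) != params$n_actions || ncol(state$c) != N_INPUTS ||
      length(state$v) != N_INPUTS) {
    stop("agent state dimensions inconsistent with parameters", call. = FALSE)
  }
  invisible(state)
}

#' Actor action values
#'
#' Computes `M_a = sum_i( m[a][i] * I_i + P * c[a][i] )` for every candidate
#' action. The perseveration term is deliberately not gated by the current
#' inputs: traces of actions executed in a different context (e.g. during the
#' home-cage inter-session period) still bias selection after a context
#' switch, which is the mechanism behind the warm-up effect.
#'
#' @param state An [agent_state()].
#' @param inputs Binary input vector of length 5 (see [encode_inputs()]).
#' @param params An [model_params()] object.
#' @return Numeric vector of length `n_actions`.
#' @export
action_values <- function(state, inputs, params) {
  check_agent_dims(state, params)
  if (length(inputs) != N_INPUTS) {
    stop("inputs must have length ", N_INPUTS, call. = FALSE)
  }
  M <- numeric(params$n_actions)
  for (i in seq_len(N_INPUTS)) M <- M + state$m[, i] * inputs[[i]]
  for (i in seq_len(N_INPUTS)) M <- M + params$persev * state$c[, i]
  M
}

#' Softmax selection probabilities over an allowed action set
#'
#' `Pr(r) = exp(M_r / T) / sum_a exp(M_a / T)` with the normalization
#' restricted to `allowed`. Computed with a shift by the maximum so that
#' large `|M| / T` cannot overflow.
#'
#' @param M Numeric vector of action values.
#' @param temperature Softmax temperature `T` (> 0).
#' @param allowed Integer indices of selectable actions.
#' @return Probabilities (same length as `allowed`) summing to 1.
#' @export
softmax_probs <- function(M, temperature, allowed = seq_along(M)) {
  if (length(allowed) == 0L) {
    stop("allowed action set is empty: misconfigured environment",
         call. = FALSE)
  }
  z <- exp((M[allowed] - max(M[allowed])) / temperature)
  z / sum(z)
}

#' Sample an action from the softmax policy
#'
#' @inheritParams softmax_probs
#' @param params An [model_params()] object supplying the temperature.
#' @param u Optional uniform(0,1) draw; taken from the R random stream when
#'   `NULL`. The selected action is the first allowed index whose cumulative
#'   probability reaches `u`.
#' @return A single action index (element of `allowed`).
#' @export
select_action <- function(M, params, allowed = seq_along(M), u = NULL) {
  p <- softmax_probs(M, params$temperature, allowed)
  if (is.null(u)) u <- stats::runif(1)
  cs <- cumsum(p)
  k <- which(u <= cs)[1L]
  if (is.na(k)) k <- length(allowed)  # guard against rounding at the tail
  allowed[k]
}

#' Reinforcement rule
#'
#' `R = r_shock` if shock is present at the next timestep (evaluated after
#' the environment has applied the action's consequences, so an escape press
#' removes the upcoming shock); otherwise `r_press` if the executed action
#' was lever-press; otherwise 0. The two costs never sum.
#'
#' @param action_was_press Logical; was the executed action lever-press?
#' @param shock_present_next Logical; is shock present at `t + 1`?
#' @param params An [model_params()] object.
#' @return Scalar reinforcement `R`.
#' @export
reinforcement_signal <- function(action_was_press, shock_present_next,
                                 params) {
  if (isTRUE(shock_present_next)) return(params$r_shock)
  if (isTRUE(action_was_press)) return(params$r_press)
  0
}

#' Critic value prediction
#'
#' `V = sum_i v[i] * I_i`.
#'
#' @inheritParams action_values
#' @return Scalar value prediction `V`.
#' @export
state_value <- function(state, inputs) {
  if (length(inputs) != N_INPUTS) {
    stop("inputs must have length ", N_INPUTS, call. = FALSE)
  }
  sum(state$v * as.numeric(inputs))
}

#' Temporal-difference prediction error
#'
#' `PE = R + gamma * V_new - V_prev`, where `V_new` is the value of the
#' post-transition inputs and `V_prev` the prediction made at the previous
#' timestep.
#'
#' @param R Scalar reinforcement.
#' @param V_new Value of the post-transition inputs.
#' @param V_prev Value prediction from the previous timestep.
#' @param params An [model_params()] object supplying `gamma`.
#' @return Scalar prediction error.
#' @export
prediction_error <- function(R, V_new, V_prev, params) {
  R + params$gamma * V_new - V_prev
}

#' Critic weight update
#'
#' `v[i] <- v[i] + alpha * PE * I_i`, then clipped to `[-|r_shock|,
#' +|r_shock|]` to keep predictions bounded. Inputs are the pre-transition
#' inputs (TD(0) credit assignment).
#'
#' @param state An [agent_state()].
#' @param PE Scalar prediction error.
#' @param inputs_prev Pre-transition input vector.
#' @param params An [model_params()] object.
#' @return The updated agent state.
#' @export
update_critic <- function(state, PE, inputs_prev, params) {
  d <- params$alpha * PE
  bound <- abs(params$r_shock)
  v <- state$v + d * as.numeric(inputs_prev)
  v[abs(v) < WEIGHT_FLOOR] <- 0
  state$v <- pmin(pmax(v, -bound), bound)
  state
}

#' Actor weight update
#'
#' For the executed action only: `m[r][i] <- m[r][i] + epsilon * (PE -
#' m[r][i]) * I_i`, floored at 0. Inputs are the pre-transition inputs.
#'
#' @inheritParams update_critic
#' @param action Index of the executed action.
#' @return The updated agent state.
#' @export
update_actor <- function(state, action, PE, inputs_prev, params) {
  row <- state$m[action, ]
  row <- row + params$epsilon * (PE - row) * as.numeric(inputs_prev)
  row[abs(row) < WEIGHT_FLOOR] <- 0
  state$m[action, ] <- pmax(0, row)
  state
}

#' Perseveration trace update
#'
#' All traces of non-executed actions decay by `trace_decay`; the executed
#' action's trace is refreshed to 1 (the whole row by default; only the
#' columns of currently active inputs when `trace_gated`).
#'
#' @inheritParams update_actor
#' @param inputs Inputs active at execution time; required when
#'   `params$trace_gated`.
#' @return The updated agent state.
#' @export
update_trace <- function(state, action, params, inputs = NULL) {
  cc <- state$c * params$trace_decay
  cc[cc < WEIGHT_FLOOR] <- 0
  state$c <- cc
  if (params$trace_gated) {
    if (is.null(inputs)) {
      stop("gated trace update requires the active inputs", call. = FALSE)
    }
    state$c[action, as.numeric(inputs) > 0] <- 1
  } else {
    state$c[action, ] <- 1
  }
  state
}

# One full learning step: observe I(t), act, observe consequences, learn.
# `action` overrides softmax selection (scripted-policy tests); the RNG is
# consumed only when `action` is NULL.
agent_step <- function(state, params, I_cur, I_next, shock_next, allowed,
                       action = NULL) {
  M <- action_values(state, I_cur, params)
  if (is.null(action)) action <- select_action(M, params, allowed)
  pressed <- action == LEVER_ACTION
  R <- reinforcement_signal(pressed, shock_next, params)
  V_new <- state_value(state, I_next)
  PE <- prediction_error(R, V_new, state$v_prev, params)
  state <- update_critic(state, PE, I_cur, params)
  state <- update_actor(state, action, PE, I_cur, params)
  state <- update_trace(state, action, params, inputs = I_cur)
  state$v_prev <- V_new
  list(state = state, action = action, pressed = pressed, R = R, PE = PE)
}
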