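#' Model parameters for the actor-critic avoidance learner
#'
#' Bundles the agent's free and fixed parameters. Defaults are the
#' Sprague-Dawley (SD) preset; see [strain_preset()] for the WKY variant.
#'
#' @param alpha Critic learning rate, in (0, 1). SD default 0.05; WKY 0.005.
#' @param epsilon Actor learning rate, in (0, 1). Default 0.005 (both strains).
#' @param temperature Explore/exploit parameter `T` (> 0) of the softmax;
#'   lower values exploit the current best action more strongly. SD 1.0;
#'   WKY 0.25.
#' @param persev Perseveration factor `P` weighting the trace of recently
#'   executed actions in the action values. SD 0.25; WKY 0.
#' @param gamma Temporal-difference discount factor, fixed at 0.9.
#' @param r_shock Reinforcement delivered when shock is present at the next
#'   timestep; a large negative value (default -4, doubled intensity -8).
#' @param r_press Cost of executing a lever-press (default -0.2).
#' @param n_actions Number of candidate actions `A` (default 100); action 1
#'   is designated lever-press.
#' @param m_init Initial value of every actor weight (default 0.01).
#' @param trace_decay Per-timestep multiplier applied to perseveration traces
#'   of non-executed actions, fixed at 0.95.
#' @param trace_gated If `TRUE`, executing an action refreshes its trace only
#'   for inputs active at execution time; the default (`FALSE`) refreshes the
#'   whole row, making the trace effectively per-action.
#'
#' @return An object of class `avoid_params` (a validated named list).
#' @examples
#' p <- model_params()
#' p$temperature
#' @export
model_params <- function(alpha = 0.05, epsilon = 0.005, temperature = 1.0,
                         persev = 0.25, gamma = 0.9, r_shock = -4,
                         r_press = -0.2, n_actions = 100L, m_init = 0.01,
                         trace_decay = 0.95, trace_gated = FALSE) {
  p <- list(alpha = alpha, epsilon = epsilon, temperature = temperature,
            persev = persev, gamma = gamma, r_shock = r_shock,
            r_press = r_press, n_actions = as.integer(n_actions),
            m_init = m_init, trace_decay = trace_decay,
            trace_gated = isTRUE(trace_gated))
  validate_params(p)
  structure(p, class = "avoid_params")
}

validate_params <- function(p) {
  stopifnot(
    is.numeric(p$alpha), p$alpha > 0, p$alpha < 1,
    is.numeric(p$epsilon), p$epsilon > 0, p$epsilon < 1,
    is.numeric(p$temperature), p$temperature > 0,
    is.numeric(p$persev), is.finite(p$persev),
    is.numeric(p$gamma), p$gamma >= 0, p$gamma <= 1,
    is.numeric(p$trace_decay), p$trace_decay > 0, p$trace_decay < 1,
    is.numeric(p$m_init), p$m_init >= 0
  )
  if (!(p$r_shock < p$r_press && p$r_press < 0)) {
    stop("model parameters require r_shock < r_press < 0", call. = FALSE)
  }
  if (p$n_actions < 2L) stop("n_actions must be at least 2", call. = FALSE)
  invisible(p)
}

#' @export
print.avoid_params <- function(x, ...) {
  cat("<avoid_params>\n")
  cat(sprintf("  alpha=%g epsilon=%g T=%g P=%g gamma=%g\n",
              x$alpha, x$epsilon, x$temperature, x$persev, x$gamma))
  cat(sprintf("  r_shock=%g r_press=%g A=%d m_init=%g trace_decay=%g%s\n",
              x$r_shock, x$r_press, x$n_actions, x$m_init, x$trace_decay,
              if (x$trace_gated) " (gated trace)" else ""))
  invisible(x)
}

as_params <- function(x) {
  if (inherits(x, "avoid_params")) return(x)
  if (inherits(x, "strain_preset")) return(x$params)
  do.call(model_params, x)
}
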