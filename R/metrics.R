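#' Per-session percent avoidance
#'
#' For each session, `100 * (#avoid outcomes) / trials_per_session`.
#'
#' @param run An `avoid_run` (see [run_experiment()]).
#' @return Numeric vector, one percentage per session.
#' @export
percent_avoidance_by_session <- function(run) {
  tr <- run$trials
  if (nrow(tr) == 0L) stop("run contains no trials", call. = FALSE)
  sessions <- sort(unique(tr$session))
  vapply(sessions, function(s) {
    100 * mean(tr$outcome[tr$session == s] == "avoid")
  }, numeric(1))
}

#' Per-session mean response latency
#'
#' Mean latency (timesteps from warning onset to first lever-press; trials
#' without a press contribute the configured trial maximum).
#'
#' @inheritParams percent_avoidance_by_session
#' @return Numeric vector, one mean latency per session.
#' @export
latency_by_session <- function(run) {
  tr <- run$trials
  if (nrow(tr) == 0L) stop("run contains no trials", call. = FALSE)
  sessions <- sort(unique(tr$session))
  vapply(sessions, function(s) mean(tr$latency[tr$session == s]), numeric(1))
}

#' Trial-by-trial avoidance curves over session blocks
#'
#' Groups sessions into consecutive blocks (3 sessions each by default) and,
#' for each within-session trial position, averages the avoidance indicator
#' over all runs and sessions in the block. A trailing partial block is
#' dropped with a warning.
#'
#' @param runs A list of `avoid_run` objects (a single run is accepted).
#' @param block_size Sessions per block (default 3).
#' @return A data frame with columns `block`, `trial`, `prop` (proportion of
#'   run-sessions with an avoidance response at that trial position).
#' @export
block_trial_curve <- function(runs, block_size = 3L) {
  runs <- as_run_list(runs)
  tr <- do.call(rbind, lapply(runs, function(r) r$trials))
  n_sessions <- max(tr$session)
  n_blocks <- n_sessions %/% block_size
  if (n_sessions %% block_size != 0L) {
    warning("dropping trailing partial block of ",
            n_sessions %% block_size, " session(s)")
  }
  if (n_blocks == 0L) stop("fewer sessions than one block", call. = FALSE)
  tr <- tr[tr$session <= n_blocks * block_size, ]
  tr$block <- (tr$session - 1L) %/% block_size + 1L
  agg <- stats::aggregate(avoid ~ block + trial,
                          data = transform(tr, avoid = outcome == "avoid"),
                          FUN = mean)
  agg <- agg[order(agg$block, agg$trial), c("block", "trial", "avoid")]
  names(agg) <- c("block", "trial", "prop")
  rownames(agg) <- NULL
  agg
}

#' Warm-up difference score
#'
#' Default variant (`"trial2_minus_trial1"`): per run, the mean over the
#' requested sessions of `avoid(trial 2) - avoid(trial 1)`; positive values
#' indicate warm-up (depressed responding on a session's first trial).
#' The `"block_edge"` variant instead compares the last two trials of the
#' session preceding the window against the first two trials of the window's
#' first session (the form used in empirical within-session analyses), again
#' signed so that positive means warm-up.
#'
#' @param runs A list of `avoid_run` objects (or a single run).
#' @param sessions Session indices of the scoring window (default 10:12, the
#'   last acquisition block under the standard schedule).
#' @param variant `"trial2_minus_trial1"` (default) or `"block_edge"`.
#' @return List with `mean`, `sem`, and the `per_run` scores.
#' @export
warmup_score <- function(runs, sessions = 10:12,
                         variant = c("trial2_minus_trial1", "block_edge")) {
  variant <- match.arg(variant)
  runs <- as_run_list(runs)
  per_run <- vapply(runs, function(r) {
    tr <- r$trials
    if (!all(sessions %in% tr$session)) {
      stop("requested sessions not present in run", call. = FALSE)
    }
    if (variant == "trial2_minus_trial1") {
      diffs <- vapply(sessions, function(s) {
        st <- tr[tr$session == s, ]
        as.numeric(st$outcome[st$trial == 2L] == "avoid") -
          as.numeric(st$outcome[st$trial == 1L] == "avoid")
      }, numeric(1))
      mean(diffs)
    } else {
      prev <- min(sessions) - 1L
      if (prev < 1L) stop("block_edge variant needs a preceding session",
                          call. = FALSE)
      pt <- tr[tr$session == prev, ]
      last_two <- utils::tail(pt[order(pt$trial), "outcome"], 2L) == "avoid"
      ft <- tr[tr$session == min(sessions) & tr$trial <= 2L, ]
      mean(last_two) - mean(ft$outcome == "avoid")
    }
  }, numeric(1))
  list(mean = mean(per_run), sem = sem(per_run), per_run = per_run)
}

# standard error of the mean across runs (n - 1 denominator); 0 for n = 1
sem <- function(x) {
  if (length(x) < 2L) {
    if (length(x) == 1L) warning("SEM undefined for a single run; reporting 0")
    return(0)
  }
  stats::sd(x) / sqrt(length(x))
}

as_run_list <- function(runs) {
  if (inherits(runs, "avoid_run")) runs <- list(runs)
  if (inherits(runs, "avoid_cohort")) runs <- runs$runs
  stopifnot(is.list(runs), all(vapply(runs, inherits, TRUE, "avoid_run")))
  # tag run indices so trial tables can be rbound
  for (i in seq_along(runs)) {
    runs[[i]]$trials$run <- if (is.null(runs[[i]]$run)) i else runs[[i]]$run
  }
  runs
}
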