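# Event-driven finite-state machine for the Go/No-Go task.
#
# The machine is deterministic given (config, seed, poke schedule). All
# randomness (trial type, then ITI duration) is drawn from a private RNG
# stream stored in the session state, so interleaving other draws between
# step calls cannot change the emitted events.

.EVENT_KINDS <- c("session_start", "iti_start", "cue_go_on", "cue_nogo_on",
                  "cue_off", "poke", "reward", "timeout_on", "timeout_off",
                  "trial_restart", "trial_end", "session_end")

# Fixed kind priority used when serializing simultaneous events: responses
# (pokes) come before consequences, consequences before state transitions.
.KIND_PRIORITY <- c(session_start = 0, poke = 1, reward = 2, cue_off = 3,
                    timeout_on = 4, timeout_off = 5, trial_restart = 6,
                    trial_end = 7, iti_start = 8, cue_go_on = 9,
                    cue_nogo_on = 9, session_end = 10)

## ---- private RNG stream ---------------------------------------------------

.rng_swap_in <- function(state) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  assign(".Random.seed", state$rng, envir = globalenv())
  old
}

.rng_swap_out <- function(state, old) {
  state$rng <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  state
}

## ---- event emission -------------------------------------------------------

.emit <- function(state, t, kind, trial = NA_integer_, side = "none") {
  n <- state$ev_n + 1L
  if (n > length(state$ev_time)) {  # grow buffers
    grow <- length(state$ev_time)
    state$ev_time  <- c(state$ev_time,  numeric(grow))
    state$ev_kind  <- c(state$ev_kind,  character(grow))
    state$ev_trial <- c(state$ev_trial, integer(grow))
    state$ev_side  <- c(state$ev_side,  character(grow))
  }
  state$ev_time[n]  <- t
  state$ev_kind[n]  <- kind
  state$ev_trial[n] <- trial
  state$ev_side[n]  <- side
  state$ev_n <- n
  state
}

.record_trial <- function(state, outcome, latency, cue_onset) {
  k <- state$tr_n + 1L
  if (k > length(state$tr_outcome)) {
    grow <- max(64L, length(state$tr_outcome))
    state$tr_index   <- c(state$tr_index,   integer(grow))
    state$tr_type    <- c(state$tr_type,    character(grow))
    state$tr_outcome <- c(state$tr_outcome, character(grow))
    state$tr_nprem   <- c(state$tr_nprem,   integer(grow))
    state$tr_latency <- c(state$tr_latency, numeric(grow))
    state$tr_cue     <- c(state$tr_cue,     numeric(grow))
  }
  state$tr_index[k]   <- state$trial_index
  state$tr_type[k]    <- state$trial_type
  state$tr_outcome[k] <- outcome
  state$tr_nprem[k]   <- state$premature
  state$tr_latency[k] <- latency
  state$tr_cue[k]     <- cue_onset
  state$tr_n <- k
  state
}

## ---- trial lifecycle ------------------------------------------------------

# Draw order is fixed for reproducibility: trial type first, then the ITI
# duration. A premature restart redraws only the ITI.
.begin_trial <- function(state, t, new_trial = TRUE) {
  cfg <- state$config
  if (new_trial) {
    state$trial_index <- state$trial_index + 1L
    state$premature <- 0L
    state$trial_type <- if (stats::runif(1) < cfg$p_nogo) "nogo" else "go"
  }
  iti <- stats::runif(1, cfg$iti_min_s, cfg$iti_max_s)
  state <- .emit(state, t, "iti_start", state$trial_index)
  state$phase <- "iti"
  state$phase_end <- t + iti
  state
}

.begin_stage0_trial <- function(state, t) {
  state$trial_index <- state$trial_index + 1L
  state$premature <- 0L
  state$trial_type <- "go"
  state <- .emit(state, t, "cue_go_on", state$trial_index,
                 state$config$active_side)
  state$cue_on <- t
  state$phase <- "ready"
  state$phase_end <- Inf
  state
}

# Fire the transition scheduled at state$phase_end (time te).
.fire_transition <- function(state, te) {
  cfg <- state$config
  ti <- state$trial_index
  if (state$phase == "iti") {
    kind <- if (state$trial_type == "go") "cue_go_on" else "cue_nogo_on"
    state <- .emit(state, te, kind, ti, cfg$active_side)
    state$cue_on <- te
    state$phase <- "cue"
    state$phase_end <- te + cfg$limited_hold_s
  } else if (state$phase == "cue") {
    # limited hold elapsed without a response
    state <- .emit(state, te, "cue_off", ti)
    if (state$trial_type == "go") {
      state <- .record_trial(state, "omission", NA_real_, state$cue_on)
    } else {
      if (cfg$reward_on_correct_rejection) {
        state <- .emit(state, te, "reward", ti)
      }
      state <- .record_trial(state, "correct_rejection", NA_real_,
                             state$cue_on)
    }
    state <- .emit(state, te, "trial_end", ti)
    if (te < cfg$session_duration_s) {
      state <- .begin_trial(state, te, new_trial = TRUE)
    } else {
      state$phase <- "idle"
      state$phase_end <- Inf
    }
  } else if (state$phase == "timeout") {
    state <- .emit(state, te, "timeout_off", ti)
    state <- .begin_stage0_trial(state, te)
  } else {
    stop("internal error: no transition scheduled in phase ", state$phase)
  }
  state
}

# Advance the machine to t_stop, firing all scheduled transitions on the way
# and ending the session when t_stop reaches its scheduled duration. With
# `strict = TRUE`, transitions scheduled exactly at t_stop are NOT fired:
# used when advancing to a poke time, so that simultaneous events resolve
# responses-before-state-transitions (a poke at the exact limited-hold
# expiry still counts as a response).
.advance <- function(state, t_stop, strict = FALSE) {
  T_end <- state$config$session_duration_s
  lim <- min(t_stop, T_end)
  while (state$phase != "done" &&
         (state$phase_end < lim || (!strict && state$phase_end == lim))) {
    te <- state$phase_end
    state <- .fire_transition(state, te)
  }
  if (state$phase != "done") state$t <- max(state$t, lim)
  if (!strict && t_stop >= T_end && state$phase != "done") {
    state <- .emit(state, T_end, "session_end")
    state$phase <- "done"
    state$t <- T_end
  }
  state
}

# Apply a poke at time t (state already advanced to t).
.apply_poke <- function(state, t) {
  cfg <- state$config
  if (state$phase == "done") return(state)
  ti <- state$trial_index
  side <- cfg$active_side
  state <- .emit(state, t, "poke", ti, side)
  if (cfg$stage == 0L) {
    if (state$phase == "ready") {
      state <- .emit(state, t, "reward", ti)
      state <- .emit(state, t, "cue_off", ti)
      state <- .record_trial(state, "hit", t - state$cue_on, state$cue_on)
      state <- .emit(state, t, "trial_end", ti)
      state <- .emit(state, t, "timeout_on", ti)
      state$phase <- "timeout"
      state$phase_end <- t + cfg$timeout_s
    }
    # pokes during the timeout have no effect
    return(state)
  }
  if (state$phase == "iti") {
    # premature response: reward omission and trial restart (fresh ITI)
    state$premature <- state$premature + 1L
    state <- .emit(state, t, "trial_restart", ti)
    state <- .begin_trial(state, t, new_trial = FALSE)
  } else if (state$phase == "cue") {
    latency <- t - state$cue_on
    state <- .emit(state, t, "cue_off", ti)
    if (state$trial_type == "go") {
      state <- .emit(state, t, "reward", ti)
      state <- .record_trial(state, "hit", latency, state$cue_on)
    } else {
      state <- .record_trial(state, "commission", latency, state$cue_on)
    }
    state <- .emit(state, t, "trial_end", ti)
    if (t < cfg$session_duration_s) {
      state <- .begin_trial(state, t, new_trial = TRUE)
    } else {
      state$phase <- "idle"
      state$phase_end <- Inf
    }
  }
  state
}

## ---- public API -----------------------------------------------------------

#' Start a Go/No-Go session
#'
#' Initializes the task state machine at `t = 0` and emits the opening
#' events: `session_start`, then for stages 1-4 the first `iti_start` (ITI
#' duration drawn uniformly from the configured bounds), or for stage 0 the
#' active cue light (`cue_go_on`), which stays on until the first poke.
#'
#' @param config a [task_config()] object.
#' @return A `gonogo_session` state object; drive it with [step_session()]
#'   or use [run_session()] for a whole session at once.
#' @export
start_session <- function(config) {
  if (!inherits(config, "gonogo_config")) {
    config <- do.call(task_config, as.list(config))
  }
  # session state lives in an environment: the event loop mutates it in
  # place, so emitting thousands of events costs no copying
  state <- list2env(
    list(config = config, t = 0, phase = "init", phase_end = Inf,
         cue_on = NA_real_, trial_index = -1L, trial_type = "go",
         premature = 0L,
         ev_time = numeric(1024L), ev_kind = character(1024L),
         ev_trial = integer(1024L), ev_side = character(1024L),
         ev_n = 0L,
         tr_index = integer(0), tr_type = character(0),
         tr_outcome = character(0), tr_nprem = integer(0),
         tr_latency = numeric(0), tr_cue = numeric(0), tr_n = 0L,
         rng = NULL, last_from = 0L),
    new.env(parent = emptyenv()))
  class(state) <- "gonogo_session"
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(config$seed)
  state$rng <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }

  old <- .rng_swap_in(state)
  state <- .emit(state, 0, "session_start")
  if (config$stage == 0L) {
    state <- .begin_stage0_trial(state, 0)
  } else {
    state <- .begin_trial(state, 0, new_trial = TRUE)
  }
  state <- .rng_swap_out(state, old)
  state
}

#' Advance a session, optionally delivering a nose poke
#'
#' Advances the state machine to `until_s`, firing every scheduled
#' transition (cue onsets/offsets, trial outcomes, stage-0 timeouts, session
#' end) in time order. If `poke` is given it must lie in
#' `(current time, until_s]`; the poke is applied at its time with premature
#' restarts, hits, commissions and stage-0 rewards resolved per the task
#' contingencies.
#'
#' @param state a `gonogo_session` from [start_session()].
#' @param poke optional poke time in seconds.
#' @param until_s time to advance to (seconds from session start).
#' @return The updated state. Events emitted by this call are in
#'   `state$last_events`; the full log so far via [session_events()].
#' @export
step_session <- function(state, poke = NULL, until_s = NULL) {
  stopifnot(inherits(state, "gonogo_session"))
  if (is.null(until_s)) {
    until_s <- if (is.null(poke)) state$config$session_duration_s
               else as.numeric(poke)
  }
  if (until_s < state$t) {
    stop("ordering error: `until_s` precedes current session time",
         call. = FALSE)
  }
  if (!is.null(poke)) {
    poke <- as.numeric(poke)
    if (poke <= state$t || poke > until_s) {
      stop("ordering error: poke time must lie in (current time, until_s]",
           call. = FALSE)
    }
  }
  from <- state$ev_n
  old <- .rng_swap_in(state)
  if (!is.null(poke)) {
    state <- .advance(state, poke, strict = TRUE)
    if (state$phase != "done") state <- .apply_poke(state, poke)
  }
  state <- .advance(state, until_s)
  state <- .rng_swap_out(state, old)
  state$last_from <- from
  state
}

#' Events emitted so far in a running session
#'
#' @param state a `gonogo_session`.
#' @param from internal offset; return events after this index.
#' @return A `gonogo_log` data frame (`time_s`, `kind`, `trial_index`,
#'   `side`).
#' @export
session_events <- function(state, from = 0L) {
  idx <- seq.int(from + 1L, length.out = state$ev_n - from)
  log <- data.frame(time_s = state$ev_time[idx],
                    kind = state$ev_kind[idx],
                    trial_index = state$ev_trial[idx],
                    side = state$ev_side[idx],
                    stringsAsFactors = FALSE)
  class(log) <- c("gonogo_log", "data.frame")
  log
}

.session_trials <- function(state) {
  idx <- seq_len(state$tr_n)
  data.frame(trial_index = state$tr_index[idx],
             trial_type = state$tr_type[idx],
             outcome = state$tr_outcome[idx],
             n_premature_restarts = state$tr_nprem[idx],
             response_latency_s = state$tr_latency[idx],
             cue_onset_s = state$tr_cue[idx],
             stringsAsFactors = FALSE)
}

#' Run a complete session against a poke schedule
#'
#' Batch driver over [step_session()]: feeds a strictly increasing schedule
#' of poke times to the machine and advances to the end of the session. The
#' result is deterministic given `(config$seed, pokes)`.
#'
#' @param config a [task_config()].
#' @param pokes numeric vector of poke times (seconds), strictly increasing.
#'   Pokes at or beyond the session end are ignored.
#' @return A `gonogo_log` data frame of the full event stream, with the
#'   engine's own trial records in `attr(, "trials")` (one row per completed
#'   trial: type, outcome, premature restarts, response latency, cue onset).
#' @examples
#' cfg <- task_config(stage = 4, session_duration_s = 60, seed = 7)
#' log <- run_session(cfg, pokes = c(5, 20.5))
#' head(log)
#' attr(log, "trials")
#' @export
run_session <- function(config, pokes = numeric(0)) {
  if (!inherits(config, "gonogo_config")) {
    config <- do.call(task_config, as.list(config))
  }
  pokes <- as.numeric(pokes)
  if (is.unsorted(pokes, strictly = TRUE)) {
    stop("ordering error: poke schedule must be strictly increasing",
         call. = FALSE)
  }
  state <- start_session(config)
  T_end <- config$session_duration_s
  pokes <- pokes[pokes > 0 & pokes < T_end]
  for (p in pokes) state <- step_session(state, poke = p, until_s = p)
  state <- step_session(state, until_s = T_end)
  log <- session_events(state)
  attr(log, "trials") <- .session_trials(state)
  attr(log, "config") <- config
  log
}

#' @export
print.gonogo_session <- function(x, ...) {
  cat(sprintf("Go/No-Go session (stage %d): t = %.3f s, phase = %s, trial %d\n",
              x$config$stage, x$t, x$phase, x$trial_index))
  cat(sprintf("  %d events emitted, %d trials completed\n", x$ev_n, x$tr_n))
  invisible(x)
}

#' @export
print.gonogo_log <- function(x, ...) {
  n_trials <- if (!is.null(attr(x, "trials"))) nrow(attr(x, "trials")) else NA
  cat(sprintf("Go/No-Go event log: %d events%s\n", nrow(x),
              if (!is.na(n_trials)) sprintf(", %d completed trials", n_trials)
              else ""))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more events\n", nrow(x) - 10L))
  invisible(x)
}
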