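# Behavioral analytics: event-log -> trial records -> session metrics, plus
# social-interaction-test phenotyping.

#' Parse an event log into trial records
#'
#' Reconstructs one record per completed trial from the raw event stream:
#' trial type from the cue kind, outcome from whether a poke fell inside the
#' cue's limited hold (go: hit/omission; no-go: commission/correct
#' rejection), premature restarts attributed to the trial that eventually
#' completed, and response latency relative to cue onset. Round-trips the
#' engine's own records losslessly.
#'
#' @param log a `gonogo_log` data frame (from [run_session()],
#'   [simulate_day()] or [read_event_log()]).
#' @return Data frame with columns `trial_index`, `trial_type`, `outcome`,
#'   `n_premature_restarts`, `response_latency_s`, `cue_onset_s`. A trial
#'   still in progress at session end is excluded; the count of excluded
#'   trials is in `attr(, "n_incomplete")` and raises a warning.
#' @export
parse_trials <- function(log) {
  stopifnot(is.data.frame(log))
  need <- c("time_s", "kind", "trial_index", "side")
  if (!all(need %in% names(log))) {
    stop("schema error: event log must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  n <- nrow(log)
  kind <- as.character(log$kind)
  time <- as.numeric(log$time_s)
  trial <- log$trial_index

  bad_kind <- which(!kind %in% .EVENT_KINDS)
  if (length(bad_kind)) {
    stop(sprintf("schema error: unknown event kind '%s' at log row %d",
                 kind[bad_kind[1]], bad_kind[1]), call. = FALSE)
  }
  if (is.unsorted(time)) {
    i <- which(diff(time) < 0)[1] + 1L
    stop(sprintf("schema error: non-monotone time at log row %d", i),
         call. = FALSE)
  }

  recs <- list()
  in_cue <- FALSE
  cue_type <- NA_character_
  cue_onset <- NA_real_
  responded_at <- NA_real_
  cur_trial <- NA_integer_
  n_prem <- 0L
  trial_open <- FALSE
  in_timeout <- FALSE

  for (i in seq_len(n)) {
    k <- kind[i]
    if (k %in% c("cue_go_on", "cue_nogo_on")) {
      if (in_cue) {
        stop(sprintf("schema error: overlapping cues at log row %d", i),
             call. = FALSE)
      }
      in_cue <- TRUE
      trial_open <- TRUE
      cue_type <- if (k == "cue_go_on") "go" else "nogo"
      cue_onset <- time[i]
      responded_at <- NA_real_
      cur_trial <- trial[i]
    } else if (k == "iti_start") {
      trial_open <- TRUE
      cur_trial <- trial[i]
    } else if (k == "poke") {
      if (in_cue && is.na(responded_at)) responded_at <- time[i]
    } else if (k == "cue_off") {
      in_cue <- FALSE
    } else if (k == "trial_restart") {
      n_prem <- n_prem + 1L
    } else if (k == "reward") {
      prev <- if (i > 1L) kind[i - 1L] else ""
      if (!prev %in% c("poke", "cue_off", "reward")) {
        stop(sprintf(
          "schema error: reward without a qualifying response at log row %d",
          i), call. = FALSE)
      }
    } else if (k == "timeout_on") {
      in_timeout <- TRUE
    } else if (k == "timeout_off") {
      in_timeout <- FALSE
    } else if (k == "trial_end") {
      if (is.na(cue_type)) {
        stop(sprintf("schema error: trial_end without a cue at log row %d",
                     i), call. = FALSE)
      }
      outcome <- if (cue_type == "go") {
        if (!is.na(responded_at)) "hit" else "omission"
      } else {
        if (!is.na(responded_at)) "commission" else "correct_rejection"
      }
      recs[[length(recs) + 1L]] <- data.frame(
        trial_index = trial[i],
        trial_type = cue_type,
        outcome = outcome,
        n_premature_restarts = n_prem,
        response_latency_s = if (!is.na(responded_at))
          responded_at - cue_onset else NA_real_,
        cue_onset_s = cue_onset,
        stringsAsFactors = FALSE)
      cue_type <- NA_character_
      cue_onset <- NA_real_
      responded_at <- NA_real_
      n_prem <- 0L
      trial_open <- FALSE
      in_cue <- FALSE
    } else if (k == "session_end") {
      # a cue presented but unresolved at session end is an incomplete
      # trial; attempts still in their ITI are simply not counted
      if (!is.na(cue_type)) {
        warning("1 incomplete trial at session end excluded", call. = FALSE)
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(trial_index = integer(0), trial_type = character(0),
               outcome = character(0), n_premature_restarts = integer(0),
               response_latency_s = numeric(0), cue_onset_s = numeric(0))
  attr(out, "n_incomplete") <- as.integer(!is.na(cue_type))
  out
}

#' Session-level Go/No-Go performance metrics
#'
#' Computes the task's headline measures from trial records: hit rate
#' (hits / go trials), commission-error rate (commissions / no-go trials),
#' premature-response counts and rate, and the correct response rate — the
#' proportion of all available rewards (hits plus correct rejections over
#' all trials, go and no-go combined) that were earned.
#'
#' @param trials data frame from [parse_trials()] (or the engine's
#'   `attr(log, "trials")`).
#' @return A `session_metrics` list: `n_go`, `n_nogo`, `hit_rate`,
#'   `commission_rate`, `premature_count`, `premature_rate`,
#'   `correct_response_rate`. A rate whose denominator is zero is `NA`
#'   (undefined), never 0. `premature_rate` is premature restarts per
#'   initiated trial attempt (completed trials + restarts).
#' @examples
#' trials <- data.frame(
#'   trial_index = 0:19,
#'   trial_type = rep(c("go", "nogo"), each = 10),
#'   outcome = c(rep("hit", 6), rep("omission", 4),
#'               rep("commission", 3), rep("correct_rejection", 7)),
#'   n_premature_restarts = 0L, response_latency_s = NA, cue_onset_s = 0)
#' m <- compute_metrics(trials)
#' m$correct_response_rate  # (6 + 7) / 20 = 0.65
#' @export
compute_metrics <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0L) {
    stop("metrics error: no completed trials", call. = FALSE)
  }
  bad <- trials$trial_type == "go" &
    !trials$outcome %in% c("hit", "omission") |
    trials$trial_type == "nogo" &
    !trials$outcome %in% c("commission", "correct_rejection")
  if (any(bad)) {
    stop("metrics error: outcome inconsistent with trial type at record ",
         which(bad)[1], call. = FALSE)
  }
  n_go <- sum(trials$trial_type == "go")
  n_nogo <- sum(trials$trial_type == "nogo")
  n_hit <- sum(trials$outcome == "hit")
  n_comm <- sum(trials$outcome == "commission")
  n_cr <- sum(trials$outcome == "correct_rejection")
  prem <- sum(trials$n_premature_restarts)
  n_total <- n_go + n_nogo
  structure(list(
    n_go = n_go,
    n_nogo = n_nogo,
    hit_rate = if (n_go > 0) n_hit / n_go else NA_real_,
    commission_rate = if (n_nogo > 0) n_comm / n_nogo else NA_real_,
    premature_count = prem,
    premature_rate = if (n_total + prem > 0) prem / (n_total + prem)
                     else NA_real_,
    correct_response_rate = if (n_total > 0) (n_hit + n_cr) / n_total
                            else NA_real_),
    class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat("Go/No-Go session metrics\n")
  cat(sprintf("  trials: %d go, %d no-go; premature restarts: %d\n",
              x$n_go, x$n_nogo, x$premature_count))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("  hit rate %s | commission rate %s | correct response rate %s\n",
              fmt(x$hit_rate), fmt(x$commission_rate),
              fmt(x$correct_response_rate)))
  invisible(x)
}

#' Per-session metrics table for a simulated cohort
#'
#' @param cohort a `gonogo_cohort` from [simulate_cohort()].
#' @return Data frame with one row per subject-day: `subject`, `group`,
#'   `day`, trial counts and all [compute_metrics()] rates.
#' @export
cohort_metrics <- function(cohort) {
  stopifnot(inherits(cohort, "gonogo_cohort"))
  rows <- lapply(names(cohort$logs), function(key) {
    log <- cohort$logs[[key]]
    agent <- attr(log, "agent")
    m <- compute_metrics(attr(log, "trials"))
    parts <- strsplit(key, "_d")[[1]]
    data.frame(subject = parts[1], group = agent$group,
               day = as.integer(parts[2]),
               n_go = m$n_go, n_nogo = m$n_nogo,
               hit_rate = m$hit_rate, commission_rate = m$commission_rate,
               premature_count = m$premature_count,
               premature_rate = m$premature_rate,
               correct_response_rate = m$correct_response_rate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Social interaction test: interaction ratio and phenotype
#'
#' The interaction ratio (IR) is time in the interaction zone with an
#' unfamiliar CD-1 target present divided by time in the same zone with the
#' target absent. Animals with IR >= 1 are classified resilient; IR < 1,
#' susceptible.
#'
#' @param time_iz_target_s,time_iz_no_target_s seconds in the interaction
#'   zone with / without the target (vectors allowed; recycled pairwise).
#' @param time_corners_s optional corner-zone time, carried through as a
#'   descriptive column.
#' @return A `sit_result` data frame with columns `time_iz_target_s`,
#'   `time_iz_no_target_s`, `time_corners_s`, `ir`, `phenotype`.
#' @examples
#' sit_classify(60, 60)$phenotype   # "resilient" (boundary case, IR = 1)
#' sit_classify(30, 60)$ir          # 0.5 -> susceptible
#' @export
sit_classify <- function(time_iz_target_s, time_iz_no_target_s,
                         time_corners_s = NA_real_) {
  if (any(time_iz_target_s < 0, na.rm = TRUE) ||
      any(time_iz_no_target_s < 0, na.rm = TRUE)) {
    stop("SIT error: zone times must be >= 0", call. = FALSE)
  }
  if (any(time_iz_no_target_s <= 0)) {
    stop("SIT error: interaction ratio undefined when no-target time is 0",
         call. = FALSE)
  }
  ir <- time_iz_target_s / time_iz_no_target_s
  out <- data.frame(time_iz_target_s = time_iz_target_s,
                    time_iz_no_target_s = time_iz_no_target_s,
                    time_corners_s = time_corners_s,
                    ir = ir,
                    phenotype = ifelse(ir >= 1, "resilient", "susceptible"),
                    stringsAsFactors = FALSE)
  class(out) <- c("sit_result", "data.frame")
  out
}
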