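# Interchange formats: event-log CSV, trace-matrix and cue-event CSV,
# strict YAML config validation. The CSV dialect is fixed: comma separator,
# dot decimal, UTF-8, header required; event times are printed with six
# decimal places so logs round-trip byte-for-byte.

#' Write an event log to CSV
#'
#' Columns `time_s,kind,trial_index,side`; times with 12 decimal places (so
#' event times round-trip to within double precision). Identical logs
#' serialize to byte-identical files.
#'
#' @param log a `gonogo_log` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(is.data.frame(log))
  lines <- c("time_s,kind,trial_index,side",
             sprintf("%.12f,%s,%s,%s",
                     log$time_s, log$kind,
                     ifelse(is.na(log$trial_index), "",
                            as.integer(log$trial_index)),
                     log$side))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an event log from CSV
#'
#' Validates the schema on read: required header, known event kinds,
#' non-decreasing times. Violations are reported with the offending file
#' line number.
#'
#' @param path CSV file written by [write_event_log()] (or conforming).
#' @return A `gonogo_log` data frame.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) {
    stop("io error: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(lines))) {
    stop("io error: empty event-log file: ", path, call. = FALSE)
  }
  if (trimws(lines[1]) != "time_s,kind,trial_index,side") {
    stop("schema error: bad header at line 1 of ", path, call. = FALSE)
  }
  if (length(lines) == 1L) {
    stop("io error: event log has a header but no events: ", path,
         call. = FALSE)
  }
  log <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(time_s = "numeric",
                                        kind = "character",
                                        trial_index = "integer",
                                        side = "character"))
  bad <- which(!log$kind %in% .EVENT_KINDS)
  if (length(bad)) {
    stop(sprintf("schema error: unknown event kind '%s' at line %d of %s",
                 log$kind[bad[1]], bad[1] + 1L, path), call. = FALSE)
  }
  if (is.unsorted(log$time_s)) {
    i <- which(diff(log$time_s) < 0)[1] + 1L
    stop(sprintf("schema error: non-monotone time_s at line %d of %s",
                 i + 1L, path), call. = FALSE)
  }
  class(log) <- c("gonogo_log", "data.frame")
  log
}

#' Write / read a trace matrix as delimited text
#'
#' The matrix is stored neurons-as-rows with a `neuron` id column; an
#' optional companion file holds the cue events
#' (`frame_index,trial_type,outcome,day`, 1-based frame indices).
#'
#' @param trace a [trace_matrix()].
#' @param path trace CSV path.
#' @param cue_path optional cue-event CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, cue_path = NULL) {
  stopifnot(inherits(trace, "trace_matrix"))
  df <- data.frame(neuron = rownames(trace$values), trace$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(cue_path) && !is.null(trace$cue_events)) {
    utils::write.csv(trace$cue_events, cue_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_trace_csv
#' @param frame_rate_hz frame rate to attach on read.
#' @export
read_trace_csv <- function(path, frame_rate_hz = 20, cue_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "neuron") {
    stop("schema error: first column of a trace CSV must be `neuron`: ",
         path, call. = FALSE)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$neuron
  colnames(values) <- NULL
  cues <- NULL
  if (!is.null(cue_path)) {
    cues <- utils::read.csv(cue_path, stringsAsFactors = FALSE)
    need <- c("frame_index", "trial_type", "outcome", "day")
    miss <- setdiff(need, names(cues))
    if (length(miss)) {
      stop("schema error: cue CSV missing column(s) ",
           paste(miss, collapse = ", "), ": ", cue_path, call. = FALSE)
    }
  }
  trace_matrix(values, frame_rate_hz, cues)
}

## ---- strict config validation --------------------------------------------

.known_fields <- list(
  task = c("stage", "session_duration_s", "iti_min_s", "iti_max_s",
           "limited_hold_s", "timeout_s", "p_nogo", "active_side",
           "reward_on_correct_rejection", "seed"),
  policy = c("p_respond_go", "p_respond_nogo", "premature_hazard_per_s",
             "latency_mean_s", "latency_sd_s", "learn_rate_go",
             "learn_rate_nogo", "p_respond_go_ceiling",
             "p_respond_nogo_floor", "group", "seed"),
  cohort = c("n_per_group", "n_days", "control", "defeated", "base_seed"),
  calcium = c("n_neurons", "n_frames", "frame_rate_hz", "baseline_rate_hz",
              "frac_modulated", "effect_gain", "cue_window_s", "rise_tau_s",
              "decay_tau_s", "transient_amplitude", "noise_sd",
              "baseline_f0", "bleach_tau_s", "cue_frames", "seed"))

.check_keys <- function(keys, kind, where) {
  known <- .known_fields[[kind]]
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    key <- unknown[1]
    dist <- utils::adist(key, known)
    hint <- known[which.min(dist)]
    stop(sprintf(
      "config error: unknown key `%s` in %s%s",
      key, where,
      if (min(dist) <= 3) sprintf(" (did you mean `%s`?)", hint) else ""),
      call. = FALSE)
  }
}

#' Read and validate a configuration file
#'
#' Reads a YAML config with a mandatory `type` field (`task`, `cohort` or
#' `calcium`) and returns the corresponding typed, defaulted,
#' invariant-checked object. Unknown keys are fatal (with a nearest-key
#' suggestion) — no silent typo tolerance.
#'
#' @param path YAML file path.
#' @return A [task_config()], [cohort_spec()] or [calcium_sim_spec()].
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) {
    stop("io error: config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$type) ||
      !raw$type %in% c("task", "cohort", "calcium")) {
    stop("config error: `type` must be one of task, cohort, calcium",
         call. = FALSE)
  }
  kind <- raw$type
  raw$type <- NULL
  if (kind == "task") {
    .check_keys(names(raw), "task", "task config")
    do.call(task_config, raw)
  } else if (kind == "calcium") {
    .check_keys(names(raw), "calcium", "calcium sim spec")
    do.call(calcium_sim_spec, raw)
  } else {
    .check_keys(names(raw), "cohort", "cohort spec")
    for (grp in c("control", "defeated")) {
      if (!is.null(raw[[grp]])) {
        .check_keys(names(raw[[grp]]), "policy",
                    sprintf("cohort %s policy", grp))
        raw[[grp]]$group <- grp
        raw[[grp]] <- do.call(agent_policy, raw[[grp]])
      }
    }
    do.call(cohort_spec, raw)
  }
}
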