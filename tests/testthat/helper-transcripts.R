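# Hand-derived session transcripts for deterministic configurations
# (iti_min == iti_max and p_nogo in {0, 1}, so every cue time is known in
# advance). Each scenario carries the config, the poke schedule, and the
# full expected event stream, written out by hand from the task rules.

# event log as a bare data frame (engine metadata attributes dropped)
strip_log <- function(x) {
  df <- as.data.frame(x)
  attr(df, "config") <- NULL
  attr(df, "trials") <- NULL
  attr(df, "agent") <- NULL
  class(df) <- "data.frame"
  rownames(df) <- NULL
  df
}

ev_row <- function(t, kind, trial = NA_integer_, side = "none") {
  data.frame(time_s = t, kind = kind, trial_index = as.integer(trial),
             side = side, stringsAsFactors = FALSE)
}

transcript <- function(...) do.call(rbind, list(...))

# shared deterministic stage-4 settings: ITI fixed 5 s, limited hold 3 s
det_cfg <- function(p_nogo, duration, reward_cr = TRUE, stage = 4) {
  task_config(stage = stage, session_duration_s = duration,
              iti_min_s = 5, iti_max_s = 5, limited_hold_s = 3,
              p_nogo = p_nogo, reward_on_correct_rejection = reward_cr,
              seed = 1)
}

scripted_scenarios <- function() {
  list(
    go_omissions = list(
      config = det_cfg(0, 20), pokes = numeric(0),
      expected = transcript(
        ev_row(0, "session_start"), ev_row(0, "iti_start", 0),
        ev_row(5, "cue_go_on", 0, "left"), ev_row(8, "cue_off", 0),
        ev_row(8, "trial_end", 0), ev_row(8, "iti_start", 1),
        ev_row(13, "cue_go_on", 1, "left"), ev_row(16, "cue_off", 1),
        ev_row(16, "trial_end", 1), ev_row(16, "iti_start", 2),
        ev_row(20, "session_end"))),
    go_hit = list(
      config = det_cfg(0, 12), pokes = 5.8,
      expected = transcript(
        ev_row(0, "session_start"), ev_row(0, "iti_start", 0),
        ev_row(5, "cue_go_on", 0, "left"), ev_row(5.8, "poke", 0, "left"),
        ev_row(5.8, "cue_off", 0), ev_row(5.8, "reward", 0),
        ev_row(5.8, "trial_end", 0), ev_row(5.8, "iti_start", 1),
        ev_row(10.8, "cue_go_on", 1, "left"),
        ev_row(12, "session_end"))),
    nogo_commission = list(
      config = det_cfg(1, 12), pokes = 5.5,
      expected = transcript(
        ev_row(0, "session_start"), ev_row(0, "iti_start", 0),
        ev_row(5, "cue_nogo_on", 0, "left"), ev_row(5.5, "poke", 0, "left"),
        ev_row(5.5, "cue_off", 0), ev_row(5.5, "trial_end", 0),
        ev_row(5.5, "iti_start", 1),
        ev_row(10.5, "cue_nogo_on", 1, "left"),
        ev_row(12, "session_end"))),
    nogo_correct_rejection_rewarded = list(
      config = det_cfg(1, 10), pokes = numeric(0),
      expected = transcript(
        ev_row(0, "session_start"), ev_row(0, "iti_start", 0),
        ev_row(5, "cue_nogo_on", 0, "left"), ev_row(8, "cue_off", 0),
        ev_row(8, "reward", 0), ev_row(8, "trial_end", 0),
        ev_row(8, "iti_start", 1), ev_row(10, "session_end"))),
    nogo_correct_rejection_unrewarded = list(
      config = det_cfg(1, 10, reward_cr = FALSE), pokes = numeric(0),
      expected = transcript(
        ev_row(0, "session_start"), ev_row(0, "iti_start", 0),
        ev_row(5, "cue_nogo_on", 0, "left"), ev_row(8, "cue_off", 0),
        ev_row(8, "trial_end", 0), ev_row(8, "iti_start", 1),
        ev_row(10, "session_end"))),
    premature_restart = list(
      config = det_cfg(0, 12), pokes = 2,
      expected = transcript(
        ev_row(0, "session_start"), ev_row(0, "iti_start", 0),
        ev_row(2, "poke", 0, "left"), ev_row(2, "trial_restart", 0),
        ev_row(2, "iti_start", 0), ev_row(7, "cue_go_on", 0, "left"),
        ev_row(10, "cue_off", 0), ev_row(10, "trial_end", 0),
        ev_row(10, "iti_start", 1), ev_row(12, "session_end"))),
    double_premature = list(
      config = det_cfg(0, 12), pokes = c(1, 3),
      expected = transcript(
        ev_row(0, "session_start"), ev_row(0, "iti_start", 0),
        ev_row(1, "poke", 0, "left"), ev_row(1, "trial_restart", 0),
        ev_row(1, "iti_start", 0), ev_row(3, "poke", 0, "left"),
        ev_row(3, "trial_restart", 0), ev_row(3, "iti_start", 0),
        ev_row(8, "cue_go_on", 0, "left"), ev_row(11, "cue_off", 0),
        ev_row(11, "trial_end", 0), ev_row(11, "iti_start", 1),
        ev_row(12, "session_end"))),
    stage0_timeout = list(
      config = task_config(stage = 0, session_duration_s = 20,
                           timeout_s = 10, seed = 1),
      pokes = c(4, 6),  # the poke at 6 falls in the timeout: no effect
      expected = transcript(
        ev_row(0, "session_start"), ev_row(0, "cue_go_on", 0, "left"),
        ev_row(4, "poke", 0, "left"), ev_row(4, "reward", 0),
        ev_row(4, "cue_off", 0), ev_row(4, "trial_end", 0),
        ev_row(4, "timeout_on", 0), ev_row(6, "poke", 0, "left"),
        ev_row(14, "timeout_off", 0), ev_row(14, "cue_go_on", 1, "left"),
        ev_row(20, "session_end"))),
    hit_at_limited_hold_boundary = list(
      config = det_cfg(0, 10), pokes = 8,  # poke exactly at cue + 3 s
      expected = transcript(
        ev_row(0, "session_start"), ev_row(0, "iti_start", 0),
        ev_row(5, "cue_go_on", 0, "left"), ev_row(8, "poke", 0, "left"),
        ev_row(8, "cue_off", 0), ev_row(8, "reward", 0),
        ev_row(8, "trial_end", 0), ev_row(8, "iti_start", 1),
        ev_row(10, "session_end"))),
    poke_at_cue_onset_is_premature = list(
      config = det_cfg(0, 12), pokes = 5,  # exactly at scheduled cue onset
      expected = transcript(
        ev_row(0, "session_start"), ev_row(0, "iti_start", 0),
        ev_row(5, "poke", 0, "left"), ev_row(5, "trial_restart", 0),
        ev_row(5, "iti_start", 0), ev_row(10, "cue_go_on", 0, "left"),
        ev_row(12, "session_end"))),
    hit_then_omission = list(
      config = det_cfg(0, 21), pokes = 5.5,
      expected = transcript(
        ev_row(0, "session_start"), ev_row(0, "iti_start", 0),
        ev_row(5, "cue_go_on", 0, "left"), ev_row(5.5, "poke", 0, "left"),
        ev_row(5.5, "cue_off", 0), ev_row(5.5, "reward", 0),
        ev_row(5.5, "trial_end", 0), ev_row(5.5, "iti_start", 1),
        ev_row(10.5, "cue_go_on", 1, "left"), ev_row(13.5, "cue_off", 1),
        ev_row(13.5, "trial_end", 1), ev_row(13.5, "iti_start", 2),
        ev_row(18.5, "cue_go_on", 2, "left"),
        ev_row(21, "session_end")))
  )
}

# the 10 go / 10 no-go hand-count fixture: 6 hits, 3 commissions
metrics_fixture_trials <- function() {
  data.frame(
    trial_index = 0:19,
    trial_type = rep(c("go", "nogo"), each = 10),
    outcome = c(rep("hit", 6), rep("omission", 4),
                rep("commission", 3), rep("correct_rejection", 7)),
    n_premature_restarts = 0L,
    response_latency_s = NA_real_,
    cue_onset_s = 0,
    stringsAsFactors = FALSE)
}
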