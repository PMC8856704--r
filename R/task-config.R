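#' Task configuration for a Go/No-Go session
#'
#' Builds the full timing/contingency parameter set for one operant session.
#' Training is staged: stage 0 is pretraining (the active nose-poke hole is
#' constantly lit; every poke is rewarded and followed by a timeout with the
#' light off), stages 1-3 are shaping parameterizations of the same state
#' machine (go-only trials with progressively shorter limited holds), and
#' stage 4 is the full Go/No-Go contingency. Unsupplied `limited_hold_s` and
#' `p_nogo` take stage-specific defaults (see Details).
#'
#' @details Stage defaults when `limited_hold_s` / `p_nogo` are `NULL`:
#' \tabular{lll}{
#'   stage \tab limited_hold_s \tab p_nogo \cr
#'   0 \tab (unused) \tab 0 \cr
#'   1 \tab 30 \tab 0 \cr
#'   2 \tab 10 \tab 0 \cr
#'   3 \tab 5 \tab 0.5 \cr
#'   4 \tab 3 \tab 0.5
#' }
#' The premature window is the variable inter-trial interval, drawn uniformly
#' from `[iti_min_s, iti_max_s]` (defaults 3-9 s). A poke during the ITI is a
#' premature response: reward omission and trial restart with a freshly drawn
#' ITI.
#'
#' @param stage integer 0-4; training stage.
#' @param session_duration_s session length in seconds (default 1800, i.e.
#'   the 30-min session).
#' @param iti_min_s,iti_max_s bounds of the uniform inter-trial (pre-cue)
#'   interval in seconds.
#' @param limited_hold_s post-cue response window in seconds; `NULL` for the
#'   stage default.
#' @param timeout_s stage-0 post-reward timeout in seconds.
#' @param p_nogo probability that a trial is a No-Go trial; `NULL` for the
#'   stage default.
#' @param active_side `"left"` or `"right"` active nose-poke hole.
#' @param reward_on_correct_rejection should withholding on a No-Go trial be
#'   rewarded? Default `TRUE`, consistent with a correct-response rate that
#'   counts available rewards on both trial types.
#' @param seed integer seed for the session's random draws (trial type, then
#'   ITI duration, in that order).
#' @return An object of class `gonogo_config` (a named list).
#' @examples
#' cfg <- task_config(stage = 4, seed = 42)
#' cfg$limited_hold_s  # stage-4 default, 3 s
#' @export
task_config <- function(stage = 4L,
                        session_duration_s = 1800,
                        iti_min_s = 3,
                        iti_max_s = 9,
                        limited_hold_s = NULL,
                        timeout_s = 10,
                        p_nogo = NULL,
                        active_side = c("left", "right"),
                        reward_on_correct_rejection = TRUE,
                        seed = 1L) {
  active_side <- match.arg(active_side)
  stage <- as.integer(stage)
  if (length(stage) != 1L || is.na(stage) || !stage %in% 0:4) {
    stop("config error: `stage` must be an integer in 0..4", call. = FALSE)
  }
  defaults <- stage_defaults(stage)
  if (is.null(limited_hold_s)) limited_hold_s <- defaults$limited_hold_s
  if (is.null(p_nogo)) p_nogo <- defaults$p_nogo

  chk_num <- function(x, name, lo = 0, strict = TRUE) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) ||
        (strict && x <= lo) || (!strict && x < lo)) {
      stop(sprintf("config error: `%s` must be a single number %s %g",
                   name, if (strict) ">" else ">=", lo), call. = FALSE)
    }
  }
  chk_num(session_duration_s, "session_duration_s")
  chk_num(iti_min_s, "iti_min_s", strict = FALSE)
  chk_num(iti_max_s, "iti_max_s")
  if (iti_min_s > iti_max_s) {
    stop("config error: `iti_min_s` must not exceed `iti_max_s`",
         call. = FALSE)
  }
  chk_num(limited_hold_s, "limited_hold_s")
  chk_num(timeout_s, "timeout_s")
  if (length(p_nogo) != 1L || !is.numeric(p_nogo) || is.na(p_nogo) ||
      p_nogo < 0 || p_nogo > 1) {
    stop("config error: `p_nogo` must be a probability in [0, 1]",
         call. = FALSE)
  }
  if (length(seed) != 1L || is.na(seed) || seed != as.integer(seed)) {
    stop("config error: `seed` must be a single integer", call. = FALSE)
  }
  structure(
    list(stage = stage,
         session_duration_s = as.numeric(session_duration_s),
         iti_min_s = as.numeric(iti_min_s),
         iti_max_s = as.numeric(iti_max_s),
         limited_hold_s = as.numeric(limited_hold_s),
         timeout_s = as.numeric(timeout_s),
         p_nogo = as.numeric(p_nogo),
         active_side = active_side,
         reward_on_correct_rejection = isTRUE(reward_on_correct_rejection),
         seed = as.integer(seed)),
    class = "gonogo_config")
}

#' Stage-specific default parameters
#'
#' Shaping-stage limited holds and No-Go mixture defaults used by
#' [task_config()] when those fields are left `NULL`.
#'
#' @param stage integer 0-4.
#' @return list with `limited_hold_s` and `p_nogo`.
#' @export
stage_defaults <- function(stage) {
  stage <- as.integer(stage)
  switch(as.character(stage),
         "0" = list(limited_hold_s = 3,  p_nogo = 0),
         "1" = list(limited_hold_s = 30, p_nogo = 0),
         "2" = list(limited_hold_s = 10, p_nogo = 0),
         "3" = list(limited_hold_s = 5,  p_nogo = 0.5),
         "4" = list(limited_hold_s = 3,  p_nogo = 0.5),
         stop("config error: `stage` must be in 0..4", call. = FALSE))
}

#' @export
print.gonogo_config <- function(x, ...) {
  cat(sprintf("Go/No-Go task config (stage %d)\n", x$stage))
  cat(sprintf("  session: %.0f s, ITI U[%.1f, %.1f] s, limited hold %.2f s\n",
              x$session_duration_s, x$iti_min_s, x$iti_max_s,
              x$limited_hold_s))
  cat(sprintf("  p(No-Go) = %.2f, active side %s, CR rewarded: %s, seed %d\n",
              x$p_nogo, x$active_side,
              x$reward_on_correct_rejection, x$seed))
  invisible(x)
}
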