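# Stochastic virtual-mouse agent that plays the Go/No-Go task through the
# state machine in closed loop. Behavior is controlled by a small policy:
# Bernoulli responses to each cue type, a Poisson hazard of premature pokes
# during the ITI, truncated-normal response latencies, and exponential
# day-by-day learning of response probabilities. The group contrast
# (control vs socially defeated) is carried only by the No-Go side: defeated
# agents learn to withhold more slowly, while go-trial engagement is matched.

#' Virtual-mouse behavioral policy
#'
#' Day-1 response parameters plus learning rates. Effective probabilities on
#' day `d` follow exponential approach curves:
#' `p_go(d) = ceiling - (ceiling - p_respond_go) * exp(-learn_rate_go (d-1))`
#' and
#' `p_nogo(d) = floor + (p_respond_nogo - floor) * exp(-learn_rate_nogo (d-1))`,
#' so commission probability decays toward `p_respond_nogo_floor` while hit
#' probability rises toward `p_respond_go_ceiling`.
#'
#' @param p_respond_go day-1 probability of responding to a Go cue.
#' @param p_respond_nogo day-1 probability of (incorrectly) responding to a
#'   No-Go cue.
#' @param premature_hazard_per_s Poisson hazard (events/s) of poking during
#'   the inter-trial interval.
#' @param latency_mean_s,latency_sd_s truncated-normal response latency
#'   parameters; latencies are truncated to `(0, limited_hold_s]`.
#' @param learn_rate_go,learn_rate_nogo per-day exponential learning rates.
#' @param p_respond_go_ceiling,p_respond_nogo_floor asymptotes of learning.
#' @param group `"control"` or `"defeated"` (label carried into outputs).
#' @param seed integer seed for this agent's random stream.
#' @return An `agent_policy` object.
#' @export
agent_policy <- function(p_respond_go = 0.60,
                         p_respond_nogo = 0.85,
                         premature_hazard_per_s = 0.02,
                         latency_mean_s = 1.0,
                         latency_sd_s = 0.5,
                         learn_rate_go = 0.35,
                         learn_rate_nogo = 0.25,
                         p_respond_go_ceiling = 0.95,
                         p_respond_nogo_floor = 0.15,
                         group = c("control", "defeated"),
                         seed = 1L) {
  group <- match.arg(group)
  chk_prob <- function(x, name) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
      stop(sprintf("policy error: `%s` must be a probability in [0, 1]",
                   name), call. = FALSE)
    }
  }
  chk_prob(p_respond_go, "p_respond_go")
  chk_prob(p_respond_nogo, "p_respond_nogo")
  chk_prob(p_respond_go_ceiling, "p_respond_go_ceiling")
  chk_prob(p_respond_nogo_floor, "p_respond_nogo_floor")
  if (premature_hazard_per_s < 0) {
    stop("policy error: `premature_hazard_per_s` must be >= 0", call. = FALSE)
  }
  if (latency_sd_s < 0) {
    stop("policy error: `latency_sd_s` must be >= 0", call. = FALSE)
  }
  if (learn_rate_go < 0 || learn_rate_nogo < 0) {
    stop("policy error: learning rates must be >= 0", call. = FALSE)
  }
  structure(list(p_respond_go = p_respond_go,
                 p_respond_nogo = p_respond_nogo,
                 premature_hazard_per_s = premature_hazard_per_s,
                 latency_mean_s = latency_mean_s,
                 latency_sd_s = latency_sd_s,
                 learn_rate_go = learn_rate_go,
                 learn_rate_nogo = learn_rate_nogo,
                 p_respond_go_ceiling = p_respond_go_ceiling,
                 p_respond_nogo_floor = p_respond_nogo_floor,
                 group = group, seed = as.integer(seed)),
            class = "agent_policy")
}

#' Effective response probabilities on a given day
#'
#' @param policy an [agent_policy()].
#' @param day testing day (1-based).
#' @return list with `p_go` and `p_nogo`, the day-adjusted response
#'   probabilities (both guaranteed in `[0, 1]`).
#' @export
policy_on_day <- function(policy, day) {
  stopifnot(day >= 1)
  decay_go <- exp(-policy$learn_rate_go * (day - 1))
  decay_ng <- exp(-policy$learn_rate_nogo * (day - 1))
  p_go <- policy$p_respond_go_ceiling -
    (policy$p_respond_go_ceiling - policy$p_respond_go) * decay_go
  p_nogo <- policy$p_respond_nogo_floor +
    (policy$p_respond_nogo - policy$p_respond_nogo_floor) * decay_ng
  list(p_go = min(max(p_go, 0), 1), p_nogo = min(max(p_nogo, 0), 1))
}

# one draw from a normal truncated to (lo, hi]
.rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  u <- stats::runif(1, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  x <- stats::qnorm(u, mean, sd)
  min(max(x, lo + 1e-9), hi)
}

#' Simulate one session of the task with a virtual mouse
#'
#' Plays the state machine in closed loop: premature pokes arrive as a
#' Poisson process during each ITI, cue responses are Bernoulli with the
#' day-adjusted probabilities of [policy_on_day()], and response latencies
#' are truncated normal within the limited hold. Deterministic given
#' `(policy$seed, config, day)`.
#'
#' @param policy an [agent_policy()].
#' @param config a [task_config()]; its `seed` field is replaced by a
#'   session seed derived from `policy$seed` and `day`.
#' @param day testing day (>= 1); sets the effective response probabilities.
#' @return A `gonogo_log` (as from [run_session()]) with the agent's group,
#'   day and effective probabilities attached as attributes.
#' @export
simulate_day <- function(policy, config, day = 1L) {
  stopifnot(inherits(policy, "agent_policy"))
  if (!inherits(config, "gonogo_config")) {
    config <- do.call(task_config, as.list(config))
  }
  if (day < 1) stop("policy error: `day` must be >= 1", call. = FALSE)
  p_eff <- policy_on_day(policy, day)
  session_seed <- (policy$seed + 7919L * as.integer(day)) %% 2147483629L
  cfg <- config
  cfg$seed <- as.integer(session_seed)
  set.seed((session_seed + 500009L) %% 2147483629L)  # agent's stream

  hazard <- policy$premature_hazard_per_s
  T_end <- cfg$session_duration_s
  state <- start_session(cfg)
  # drive the engine internals directly: agent and engine draws interleave
  # in one seeded stream, so the session is still fully deterministic
  old_rng <- .rng_swap_in(state)
  on.exit(.rng_swap_out(state, old_rng), add = TRUE)
  poke_then_advance <- function(t_poke) {
    .advance(state, t_poke, strict = TRUE)
    if (state$phase != "done") .apply_poke(state, t_poke)
  }
  while (state$phase != "done") {
    ph <- state$phase
    if (ph == "iti") {
      t_poke <- if (hazard > 0) state$t + stats::rexp(1, hazard) else Inf
      if (t_poke < state$phase_end && t_poke < T_end) {
        poke_then_advance(t_poke)
      } else {
        .advance(state, min(state$phase_end, T_end))
      }
    } else if (ph == "cue") {
      p_resp <- if (state$trial_type == "go") p_eff$p_go else p_eff$p_nogo
      if (stats::runif(1) < p_resp) {
        lat <- .rtruncnorm1(policy$latency_mean_s, policy$latency_sd_s,
                            0, cfg$limited_hold_s)
        t_poke <- state$cue_on + lat
        if (t_poke <= state$t) t_poke <- state$t + 1e-6
        if (t_poke < T_end) poke_then_advance(t_poke)
        else .advance(state, T_end)
      } else {
        .advance(state, min(state$phase_end, T_end))
      }
    } else if (ph == "ready") {  # stage 0: light on, waiting
      t_poke <- state$t +
        stats::rexp(1, 1 / max(policy$latency_mean_s, 1e-6))
      if (t_poke < T_end) poke_then_advance(t_poke)
      else .advance(state, T_end)
    } else {  # timeout or idle: wait out
      .advance(state, min(state$phase_end, T_end))
    }
  }
  log <- session_events(state)
  attr(log, "trials") <- .session_trials(state)
  attr(log, "config") <- cfg
  attr(log, "agent") <- list(group = policy$group, day = day,
                             p_go_effective = p_eff$p_go,
                             p_nogo_effective = p_eff$p_nogo,
                             premature_hazard_per_s = hazard,
                             seed = policy$seed)
  log
}

#' Cohort specification
#'
#' @param n_per_group subjects per group (>= 1).
#' @param n_days testing days per subject (default 14).
#' @param control,defeated [agent_policy()] templates for the two groups
#'   (the `seed` fields of the templates are ignored; per-subject seeds are
#'   derived from `base_seed`).
#' @param base_seed integer; root of all per-subject seed streams.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = 12L, n_days = 14L,
                        control = agent_policy(group = "control"),
                        defeated = agent_policy(group = "defeated",
                                                learn_rate_nogo = 0.10),
                        base_seed = 1L) {
  if (n_per_group < 1) {
    stop("cohort error: `n_per_group` must be >= 1", call. = FALSE)
  }
  if (n_days < 1) stop("cohort error: `n_days` must be >= 1", call. = FALSE)
  stopifnot(inherits(control, "agent_policy"),
            inherits(defeated, "agent_policy"))
  control$group <- "control"
  defeated$group <- "defeated"
  structure(list(n_per_group = as.integer(n_per_group),
                 n_days = as.integer(n_days),
                 control = control, defeated = defeated,
                 base_seed = as.integer(base_seed)),
            class = "cohort_spec")
}

#' Simulate a two-group cohort across days
#'
#' Simulates `n_per_group` subjects per group for `n_days` days each, with
#' independent per-subject seed streams derived from `base_seed` (changing
#' one subject's seed changes only that subject's logs).
#'
#' @param spec a [cohort_spec()].
#' @param config a [task_config()] shared by all sessions.
#' @return A `gonogo_cohort`: list with `logs` (named
#'   `<group>_s<subject>_d<day>`), `truth` (data frame of per-subject/day
#'   ground-truth policy parameters), and the spec/config used.
#' @export
simulate_cohort <- function(spec, config) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!inherits(config, "gonogo_config")) {
    config <- do.call(task_config, as.list(config))
  }
  groups <- c("control", "defeated")
  logs <- list()
  truth <- vector("list", 2L * spec$n_per_group * spec$n_days)
  k <- 0L
  for (gi in seq_along(groups)) {
    template <- spec[[groups[gi]]]
    for (s in seq_len(spec$n_per_group)) {
      pol <- template
      pol$seed <- (spec$base_seed + 104729L * gi + 389L * s) %% 2147483629L
      for (day in seq_len(spec$n_days)) {
        log <- simulate_day(pol, config, day)
        key <- sprintf("%s_s%02d_d%02d", groups[gi], s, day)
        logs[[key]] <- log
        p_eff <- policy_on_day(pol, day)
        k <- k + 1L
        truth[[k]] <- data.frame(subject = sprintf("%s_s%02d", groups[gi], s),
                                 group = groups[gi], day = day,
                                 p_go_effective = p_eff$p_go,
                                 p_nogo_effective = p_eff$p_nogo,
                                 premature_hazard_per_s =
                                   pol$premature_hazard_per_s,
                                 seed = pol$seed,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(logs = logs, truth = do.call(rbind, truth),
                 spec = spec, config = config),
            class = "gonogo_cohort")
}

#' @export
print.agent_policy <- function(x, ...) {
  cat(sprintf("Virtual-mouse policy (%s)\n", x$group))
  cat(sprintf("  day 1: P(respond|go) = %.2f, P(respond|nogo) = %.2f\n",
              x$p_respond_go, x$p_respond_nogo))
  cat(sprintf("  learning: go %.2f/day -> %.2f, nogo %.2f/day -> %.2f\n",
              x$learn_rate_go, x$p_respond_go_ceiling,
              x$learn_rate_nogo, x$p_respond_nogo_floor))
  cat(sprintf("  premature hazard %.3f/s, latency %.2f +/- %.2f s, seed %d\n",
              x$premature_hazard_per_s, x$latency_mean_s, x$latency_sd_s,
              x$seed))
  invisible(x)
}

#' @export
print.gonogo_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d/group x %d days (%d sessions)\n",
              x$spec$n_per_group, x$spec$n_days, length(x$logs)))
  invisible(x)
}
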