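# Replicate-cohort simulation studies used to validate the statistical
# machinery end to end: type-I calibration of the mixed ANOVA on null
# cohorts, power of the day x group interaction under the defeated-group
# learning deficit, and the calcium modulation-screen operating
# characteristics on ground-truth synthetic data. The within-subject tests
# are Greenhouse-Geisser corrected: session-level proportions are
# heteroscedastic across days (both the response probability and the trial
# count change with learning), which inflates the uncorrected interaction F.

#' Type-I calibration of the cohort ANOVA on null cohorts
#'
#' Simulates replicate cohorts whose two groups share an identical behavioral
#' template (no group effect by construction), runs the mixed-design ANOVA on
#' per-session commission rates, and reports how often the day x group
#' interaction is rejected. With a calibrated test the rejection rate is
#' close to `alpha`.
#'
#' @param n_replicates number of replicate cohorts.
#' @param n_per_group,n_days cohort dimensions.
#' @param session_duration_s session length used for the simulated sessions.
#' @param base_seed integer; replicate seeds derive from it.
#' @param alpha nominal level.
#' @return list with `rejection_rate`, the vector of interaction `p_values`,
#'   and the study parameters.
#' @export
anova_null_calibration <- function(n_replicates = 200, n_per_group = 6,
                                   n_days = 4, session_duration_s = 300,
                                   base_seed = 1, alpha = 0.05) {
  cfg <- task_config(stage = 4, session_duration_s = session_duration_s,
                     seed = 1)
  template <- agent_policy()  # same template for both groups -> true null
  defeated_same <- template
  defeated_same$group <- "defeated"
  p <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    spec <- cohort_spec(n_per_group = n_per_group, n_days = n_days,
                        control = template, defeated = defeated_same,
                        base_seed = (base_seed + 7177L * r) %% 2147483629L)
    m <- cohort_metrics(simulate_cohort(spec, cfg))
    a <- rm_anova(m, "commission_rate", gg_correction = TRUE)
    p[r] <- a$p_gg[a$effect == "day:group"]
  }
  list(rejection_rate = mean(p < alpha), p_values = p,
       n_replicates = n_replicates, n_per_group = n_per_group,
       n_days = n_days, alpha = alpha)
}

#' Power to recover the defeated-group inhibitory-control deficit
#'
#' Simulates replicate cohorts in which the defeated group learns to
#' withhold No-Go responses more slowly than controls (the groups' go-trial
#' parameters are matched), and reports (i) the fraction of cohorts with a
#' significant day x group interaction on the commission rate and (ii) the
#' same fraction for the hit rate, which is null by construction and should
#' stay at the nominal level.
#'
#' @inheritParams anova_null_calibration
#' @return list with `power_commission`, `hit_interaction_rate`, the
#'   p-value vectors, and the study parameters.
#' @export
group_effect_power_study <- function(n_replicates = 100, n_per_group = 12,
                                     n_days = 14, session_duration_s = 360,
                                     base_seed = 1, alpha = 0.05) {
  cfg <- task_config(stage = 4, session_duration_s = session_duration_s,
                     seed = 1)
  p_comm <- p_hit <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    spec <- cohort_spec(n_per_group = n_per_group, n_days = n_days,
                        base_seed = (base_seed + 4801L * r) %% 2147483629L)
    m <- cohort_metrics(simulate_cohort(spec, cfg))
    a <- rm_anova(m, "commission_rate", gg_correction = TRUE)
    b <- rm_anova(m, "hit_rate", gg_correction = TRUE)
    p_comm[r] <- a$p_gg[a$effect == "day:group"]
    p_hit[r] <- b$p_gg[b$effect == "day:group"]
  }
  list(power_commission = mean(p_comm < alpha),
       hit_interaction_rate = mean(p_hit < alpha),
       p_commission = p_comm, p_hit = p_hit,
       n_replicates = n_replicates, n_per_group = n_per_group,
       n_days = n_days, alpha = alpha)
}

#' Operating characteristics of the cue-modulation screen
#'
#' Generates a synthetic session with a known modulated subset (default
#' 10% of neurons, rate gain 3 within the 10-s post-cue window), runs the
#' full pipeline (z-score, peri-cue alignment, rank-sum screen at the
#' stringent cutoff) and scores it against ground truth. A companion
#' pure-noise session (no transients) measures the false-positive rate of
#' the screen on independent null neurons.
#'
#' @param n_neurons neurons per session.
#' @param n_trials cue presentations (30-s trial period).
#' @param frac_modulated,effect_gain ground-truth modulation parameters.
#' @param cutoff screen cutoff (default 1e-4).
#' @param seed integer seed.
#' @return list with `sensitivity`, `fdr`, `median_effect_d` (realized
#'   standardized pre/post effect size of the modulated set),
#'   `null_flag_rate` (fraction of pure-noise neurons flagged), and counts.
#' @export
modulation_screen_study <- function(n_neurons = 2000, n_trials = 50,
                                    frac_modulated = 0.1, effect_gain = 3,
                                    cutoff = 1e-4, seed = 1) {
  cues <- as.integer(seq(100, by = 600, length.out = n_trials))
  n_frames <- max(cues) + 210L
  spec <- calcium_sim_spec(n_neurons = n_neurons, n_frames = n_frames,
                           frac_modulated = frac_modulated,
                           effect_gain = effect_gain,
                           cue_frames = cues, seed = seed)
  sim <- simulate_calcium(spec)
  al <- align_to_cues(zscore_traces(sim$trace))
  res <- detect_modulated(al, cutoff = cutoff)
  truth_ids <- sim$truth$modulated_ids
  detected <- which(res$modulated)
  sensitivity <- mean(truth_ids %in% detected)
  fdr <- if (length(detected)) mean(!(detected %in% truth_ids)) else 0

  pre <- al$time_s < 0
  post <- al$time_s >= 0
  d_vals <- vapply(truth_ids, function(i) {
    M <- al$z[i, , ]
    a <- rowMeans(M[, post, drop = FALSE])
    b <- rowMeans(M[, pre, drop = FALSE])
    (mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
  }, numeric(1))

  spec0 <- calcium_sim_spec(n_neurons = n_neurons, n_frames = n_frames,
                            baseline_rate_hz = 0, frac_modulated = 0,
                            cue_frames = cues,
                            seed = (seed + 104659L) %% 2147483629L)
  sim0 <- simulate_calcium(spec0)
  res0 <- detect_modulated(align_to_cues(zscore_traces(sim0$trace)),
                           cutoff = cutoff)
  list(sensitivity = sensitivity, fdr = fdr,
       median_effect_d = stats::median(d_vals),
       null_flag_rate = mean(res0$modulated),
       n_detected = length(detected), n_modulated = length(truth_ids),
       n_neurons = n_neurons, n_trials = n_trials, cutoff = cutoff)
}

#' Early- vs late-training population activity contrast
#'
#' Emulates the day-1 versus day-14 comparison: two synthetic sessions with
#' identical structure except that the late session's cue-locked rate gain
#' is doubled. Returns the fraction of post-cue samples at which the late
#' session's population median z-scored dF/F exceeds the early one's.
#'
#' @param n_neurons neurons per session (half cue-modulated).
#' @param n_trials cue presentations per session.
#' @param gain_day1 cue-locked rate gain on day 1 (day 14 uses twice this).
#' @param seed integer seed.
#' @return list with `fraction_post_above`, and the two `population_median`
#'   tables (`median_day1`, `median_day14`).
#' @export
day_contrast_study <- function(n_neurons = 100, n_trials = 50,
                               gain_day1 = 3, seed = 1) {
  cues <- as.integer(seq(200, by = 600, length.out = n_trials))
  n_frames <- max(cues) + 210L
  mk <- function(gain, day, s) {
    labels <- data.frame(
      trial_type = rep(c("go", "nogo"), length.out = n_trials),
      outcome = rep(c("hit", "correct_rejection"), length.out = n_trials),
      day = day)
    spec <- calcium_sim_spec(n_neurons = n_neurons, n_frames = n_frames,
                             frac_modulated = 0.5, effect_gain = gain,
                             cue_frames = cues, cue_labels = labels,
                             seed = s)
    population_median(
      align_to_cues(zscore_traces(simulate_calcium(spec)$trace)))
  }
  m1 <- mk(gain_day1, 1L, seed)
  m14 <- mk(2 * gain_day1, 14L, (seed + 60013L) %% 2147483629L)
  post <- m1$time_s > 0
  list(fraction_post_above = mean(m14$median[post] > m1$median[post]),
       median_day1 = m1, median_day14 = m14)
}
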