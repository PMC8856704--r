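---
title: "Methods: Go/No-Go task simulation and peri-cue calcium analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Go/No-Go task simulation and peri-cue calcium analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This package is a pure-software counterpart of an operant Go/No-Go setup
for mice with head-mounted miniscope calcium imaging. It has three layers:
a deterministic task state machine plus a stochastic virtual-mouse agent
that generates behavioral event logs; behavioral analytics (trial parsing,
session metrics, social-interaction phenotyping, mixed-design ANOVA); and a
calcium-trace pipeline (photobleaching correction, z-scored dF/F, peri-cue
alignment, population medians, rank-sum modulation screening, heat maps)
paired with a ground-truth synthetic transient generator. This vignette
documents the models, the tunable parameters, and the numerical and design
choices.

## The task state machine

A stage-4 (full task) trial is: a variable inter-trial interval (ITI) drawn
uniformly from `[iti_min_s, iti_max_s]` (default 3-9 s), then a Go cue
(light) or a No-Go cue (light plus tone) with probability `p_nogo`
(default 0.5), active for the limited hold (default 3 s). A nose poke
within the limited hold of a Go cue is a *hit* (rewarded); the same poke on
a No-Go cue is a *commission error* (reward omitted). No response yields an
*omission* (Go) or a *correct rejection* (No-Go); correct rejections are
rewarded by default (`reward_on_correct_rejection`), consistent with a
correct-response rate defined as the fraction of all available rewards
earned on both trial types. A poke during the ITI is a *premature
response*: reward omission and trial restart with a freshly drawn ITI (the
trial keeps its index and its drawn type; only the ITI is redrawn).

Stage 0 is pretraining: the active hole is constantly lit, every poke is
rewarded and followed by a timeout (default 10 s) with the light off during
which pokes have no effect. Stages 1-3 are parameterizations of the same
machine (go-only trials with longer limited holds; see
`stage_defaults()`); the exact shaping parameters of a physical rig are
rig-specific, so all of them are exposed in `task_config()` rather than
hard-coded.

Numerical conventions:

* Time is continuous float seconds. Simultaneous events are emitted in a
  fixed priority order — responses before consequences before state
  transitions — so a poke at exactly the limited-hold expiry is still a
  response (latency equal to the limited hold is a hit), and a poke at the
  exact scheduled cue onset is still premature (the ITI has not ended when
  responses are resolved).
* All session randomness (trial type, then ITI duration — in that draw
  order) comes from a private per-session RNG stream seeded by
  `config$seed`, stored inside the session state. Identical
  `(config, seed, poke schedule)` therefore give byte-identical serialized
  logs regardless of what else draws random numbers between `step_session()`
  calls.
* Event logs serialize to a fixed CSV dialect (comma, dot decimal, UTF-8,
  header `time_s,kind,trial_index,side`, times with 12 decimals) and
  round-trip losslessly.

## The virtual mouse

The agent plays the machine in closed loop. Its policy has three parts,
all in `agent_policy()`:

* **Cue responses**: Bernoulli with day-adjusted probabilities. Learning
  follows exponential approach curves:
  `p_go(d) = ceiling - (ceiling - p_go(1)) exp(-r_go (d-1))` and
  `p_nogo(d) = floor + (p_nogo(1) - floor) exp(-r_nogo (d-1))`. This is the
  minimal two-parameter model that reproduces the qualitative time course
  (performance improves over the 14 testing days); no functional form is
  implied by the behavioral data themselves.
* **Premature pokes**: a Poisson process with constant hazard (default
  0.02/s) during ITIs.
* **Latencies**: truncated normal within `(0, limited_hold]` (default
  1.0 +/- 0.5 s).

The group contrast is carried *only* by the No-Go side: the defeated
template halves the no-go learning rate (0.10/day vs 0.25/day) while both
groups share identical go-trial parameters. This mirrors the empirical
dissociation this class of experiments reports: stressed animals make more
commission errors while go-trial engagement is indistinguishable. Default
day-1 probabilities are 0.60 (go; rising to a 0.95 ceiling) and 0.85
(no-go; decaying to a 0.15 floor) — chosen once as plausible early-training
values for food-restricted mice; there are no published per-day numbers to
calibrate against, so these synthetic effect sizes are study conditions,
not estimates.

What the agent does **not** model: within-session satiety or fatigue,
per-subject random effects (between-subject variability is purely the
binomial sampling noise of finite trial counts), sequential dependencies
between trials, and any biophysical decision process. Passing cohort-level
tests therefore shows that the *statistical machinery* behaves correctly
under known ground truth, not that real mice behave like the agent.

## Behavioral analytics

`parse_trials()` reconstructs trial records purely from the event stream
(the engine's own records are used only as a test oracle), inferring the
outcome from the cue kind and the presence of a poke during the cue.
Premature restarts are attributed to the trial that eventually completes. A
cue left unresolved at session end is excluded with a warning; attempts
still in their ITI at session end are simply not counted.

`compute_metrics()` reports hit rate (hits/go trials), commission rate
(commissions/no-go trials), the correct response rate
(hits + correct rejections over all trials), and premature counts. The
premature *rate* needs a denominator the task literature does not fix; we
use restarts per initiated attempt (completed trials + restarts), a stable
proportion in [0, 1]; the raw count is also reported. A rate whose
denominator is zero is `NA`, never 0.

`sit_classify()` computes the social-interaction ratio
IR = time in interaction zone with target / without target, classifying
IR >= 1 as resilient and IR < 1 as susceptible; the boundary is exact (an
IR of `1 - 1e-12` is susceptible). Corner-zone time is carried through
descriptively.

### Mixed-design ANOVA

`rm_anova()` implements the two-way mixed (split-plot) ANOVA — between
factor group, within factor day — with sums of squares computed directly
from cell and marginal means: the between-subjects stratum tests group
against subject(group); the within stratum tests day and day x group
against the day x subject(group) residual. It requires a complete balanced
subject x day table with equal group sizes and refuses missing cells (no
imputation). Two flags matter in practice:

* `arcsine`: the arcsine-square-root transform for proportions.
* `gg_correction`: Greenhouse-Geisser sphericity correction; epsilon is
  estimated from the pooled within-group covariance of the subject x day
  matrix (double-centered trace form, clamped to `[1/(d-1), 1]`) and
  multiplies the within-stratum degrees of freedom.

The validation studies (`anova_null_calibration()`,
`group_effect_power_study()`) use the GG-corrected interaction test. The
reason is empirical and worth stating: session-level commission
proportions are heteroscedastic across days — both the response
probability and the realized number of no-go trials change as the agent
learns — and the uncorrected interaction test then runs above its nominal
level (about 8% at alpha = 0.05 on null cohorts in our calibration runs);
the GG correction restores it to about 5.5%. The uncorrected test remains
the default of `rm_anova()` itself so both reporting styles are available.

Chosen study sizes (one CPU, a few minutes each): calibration uses 200
replicate null cohorts of 6 subjects/group x 4 days with 300-s sessions;
the power study uses 100 replicate cohorts of 12 subjects/group x 14 days
with 360-s sessions, which recovers the commission-rate day x group
interaction in about 90% of cohorts while the hit-rate interaction stays at
the nominal level. Session lengths are the package's chosen study sizes:
they give ~40-50 trials per session, enough for stable session
proportions.

## The calcium pipeline

Input is a neurons x frames fluorescence matrix at a fixed frame rate
(default 20 Hz, i.e. 36,000 frames for a 30-min session) with cue-event
annotations — the output of upstream cell detection, which is deliberately
out of scope.

* **Bleaching correction** (`correct_drift()`): per neuron, a running
  baseline is the rolling 8th percentile over a centered 30-s window
  (truncated at the session edges), and dF/F = (F - baseline)/baseline.
  Window and percentile are conventional GCaMP baselining values and both
  are configurable. Numerically the percentile is evaluated on a regular
  grid of window centers (step = window/20) and linearly interpolated
  between centers — for a 30-s window at 20 Hz this is exact to well below
  the noise floor and ~20x faster than a dense evaluation. A non-positive
  baseline is an error directing the user to a higher percentile.
* **z-scoring** (`zscore_traces()`): per neuron over the whole session.
  Whole-session scaling is the stable choice; per-trial baselining is a
  different analysis, not a flag of this one. Zero-variance neurons are
  excluded with a warning rather than propagating NaN.
* **Alignment** (`align_to_cues()`): windows from 3 s before to 10 s after
  each cue onset; at 20 Hz that is `round(3*20) + round(10*20) + 1 = 261`
  samples with onset at sample 61 (time 0). Cue onsets map to their nearest
  frame; cues whose window leaves the session are dropped with a warning.
* **Population median** (`population_median()`): median across all selected
  neurons x trials at each peri-cue sample, with the (unscaled) median
  absolute deviation about that median; optionally split by trial type,
  outcome, correct/incorrect, or day. Empty split levels are absent from
  the output, not zero.
* **Modulation screen** (`detect_modulated()`): per neuron, per-trial mean
  activity in the pre window (times < 0, i.e. -3..0 s) versus the post
  window (times >= 0, 0..10 s), compared with a two-sided Wilcoxon rank-sum
  test and the stringent fixed cutoff p < 1e-4. The pre/post windows are
  the displayed analysis window; the per-trial means make the test's units
  trials, not autocorrelated samples. The test is exact for small untied
  samples and a tie-corrected normal approximation otherwise
  (`stats::wilcox.test`); the test suite checks it against a full
  enumeration oracle for up to 8 trials. No multiplicity correction is
  applied beyond the stringent cutoff, matching the fixed-cutoff screening
  convention; a Benjamini-Hochberg option exists but is off by default.
  One caveat the synthetic ground truth exposes: with transient-bearing
  (autocorrelated, right-skewed) null neurons the unequal pre/post window
  lengths make the extreme tail of the screen slightly anticonservative;
  at the 1e-4 cutoff this costs a small, measured false-discovery fraction
  (well under 0.1 in the ground-truth study), and on i.i.d. noise the
  screen is clean.
* **Heat maps** (`heatmap_matrix()`): per selected neuron the trial-median
  time course scaled by its maximum absolute value (each row in [-1, 1]
  with at least one |1|), rows sorted by peak latency ascending so
  between-day synchronization is visible; all-zero rows are left as zeros,
  flagged, and sorted last.

## The synthetic calcium generator

Each neuron fires Poisson transient events at `baseline_rate_hz`; a
`frac_modulated` subset fires at `effect_gain` times that rate inside the
`cue_window_s` (default 10 s) after every cue. Events are convolved with an
amplitude-normalized double-exponential kernel (`rise_tau_s` 0.07 s,
`decay_tau_s` 0.7 s — fast-indicator-like constants), scaled by
`transient_amplitude`, plus Gaussian noise on a positive baseline offset,
all multiplied by a single-exponential bleaching curve
(`exp(-t/bleach_tau_s)`; 0 disables). Convolution is FFT-based with
zero-padding to a 5-smooth length. Normalizing the kernel to unit peak
makes transient amplitude frame-rate invariant.

Defaults were chosen once as a moderately active cortical population under
a fast indicator: 0.15 events/s baseline, transient amplitude 0.6 of
baseline fluorescence, noise SD 0.05, rate gain 3. Under these conditions
the realized standardized pre/post effect size of modulated neurons at 50
trials is about d = 1.4, and the screen attains sensitivity >= 0.9 at
false-discovery <= 0.1. The generator does not model neuropil
contamination, motion, per-neuron kinetic heterogeneity, or
event-amplitude variability — so pipeline results on it validate the
analysis code, not biological effect sizes.

The day-1 vs day-14 emulation (`day_contrast_study()`) builds two sessions
with half the population cue-modulated and the late session's gain doubled;
the late session's post-cue population median exceeds the early one's at
~95% of post-cue samples. Two opposing forces shape this number:
whole-session z-scoring compresses the more active late session (lowering
its baseline median) while the doubled evoked rate raises its post-cue
median; with 30-s trial periods the evoked effect dominates everywhere
except the first few hundred milliseconds while transients rise.

## Degenerate inputs and edge policy

Undefined rates are `NA`, never 0. Zero error variance in the ANOVA is
reported as degenerate (F = NA), not as F = 0. A rank-sum comparison of
completely identical samples returns p = 1. Empty split levels are absent.
Empty event-log files, unknown event kinds, non-monotone timestamps, and
unknown config keys (with a nearest-key suggestion) are all hard errors
with the offending line or key named — simulation studies are too easy to
silently misconfigure otherwise.

## Reproducibility

Every file-writing pipeline (`simulate_cohort_files()`,
`simulate_calcium_files()`) records a self-contained `manifest.json` — the
command, the full generating configuration, all seeds, and output md5s.
`replay_manifest()` re-executes the recorded command; because all
randomness is seeded from the recorded configuration, replays are
byte-identical for CSV outputs. Seeds are kept below 2^31.

## Known limitations

* Physical-rig shaping parameters (stage advancement criteria, exact cue
  durations) are configurable defaults, not measured values.
* The agent's cohort structure has no subject-level random effects; real
  cohorts have larger between-subject variance, so the power study's
  sample sizes do not transfer to animal experiments.
* The calcium generator's Poisson-and-kernel model is a deliberately
  simple stand-in for real GCaMP recordings; detection performance on it
  is an upper bound.
* No HDF5 trace I/O; the delimited-matrix CSV format is the interchange
  format.
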