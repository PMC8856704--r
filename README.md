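# gonogo

Simulation and analysis toolkit for the mouse Go/No-Go operant task with
miniscope calcium imaging — entirely in software. It is aimed at
behavioral-neuroscience groups who want to (i) prototype and validate the
statistics of a Go/No-Go study (inhibitory control after adolescent social
defeat stress is the motivating design) before running animals, and (ii)
run the standard peri-cue calcium-trace analyses on extracted fluorescence
matrices, with a ground-truth synthetic generator to verify every step.

## What it implements

**Task engine.** A deterministic event-driven finite-state machine for the
task and its training stages (stage 0 pretraining through the full stage-4
contingency). A stage-4 trial: variable ITI uniform on [3, 9] s (pokes
here are *premature* → reward omission and trial restart), then a Go cue
(light) or No-Go cue (light + tone) with a 3-s limited hold. Hits are
rewarded, commission errors are not; correct rejections are rewarded by
default. Sessions are byte-reproducible given `(config, seed, pokes)`.

**Virtual mouse.** A stochastic agent playing the engine in closed loop:
Bernoulli cue responses with exponential day-by-day learning, Poisson
premature-poke hazard, truncated-normal latencies. The defeated group
learns to withhold No-Go responses more slowly (go-side parameters are
matched), reproducing the stress phenotype's statistical signature in
simulated cohorts.

**Behavioral analytics.** Trial parsing from event logs; hit / commission /
premature / correct-response rates; social-interaction-test interaction
ratio IR = t_target / t_no-target with the IR >= 1 resilient threshold; and
a mixed-design repeated-measures ANOVA (between: group; within: day) with
first-principles sums of squares,

    F_group = MS_group / MS_subj(group),
    F_day, F_day:group = MS_effect / MS_day x subj(group),

with optional arcsine-square-root transform and Greenhouse–Geisser
correction (epsilon from the pooled within-group covariance).

**Calcium pipeline.** Sliding-window photobleaching correction (rolling
8th-percentile baseline, 30-s window → dF/F), whole-session z-scoring,
peri-cue alignment (−3..+10 s → 261 samples at 20 Hz), population
median ± MAD time courses (split by trial type / outcome / day),
cue-modulation screening (two-sided Wilcoxon rank-sum on per-trial pre vs
post means, cutoff p < 1e-4), and peak-latency-sorted heat maps normalized
to [−1, 1].

**Synthetic calcium.** Poisson transients convolved with an
amplitude-normalized double-exponential kernel (rise 0.07 s, decay 0.7 s),
cue-locked rate gain in a modulated subset, Gaussian noise, exponential
bleaching — with full ground truth for end-to-end validation.

## Worked example

```r
library(gonogo)

cfg <- task_config(stage = 4, session_duration_s = 1800, seed = 1)
pol <- agent_policy(group = "defeated", learn_rate_nogo = 0.10, seed = 7)
log <- simulate_day(pol, cfg, day = 14)
log
#> Go/No-Go event log: 1264 events, 217 completed trials
#>       time_s          kind trial_index side
#> 1   0.000000 session_start          NA none
#> 2   0.000000     iti_start           0 none
#> 3   4.453388   cue_nogo_on           0 left
#> 4   5.365239          poke           0 left
#> ...

compute_metrics(parse_trials(log))
#> Go/No-Go session metrics
#>   trials: 98 go, 119 no-go; premature restarts: 30
#>   hit rate 0.939 | commission rate 0.328 | correct response rate 0.793
```

By day 14 this defeated agent pokes reliably on Go trials (hit rate 0.94)
but still fails to withhold on a third of No-Go trials (commission rate
0.33) — a control agent's commission rate would be near its 0.15 floor by
then. The correct response rate (fraction of all available rewards earned,
both trial types) is 0.79.

```r
sit_classify(c(82, 45), c(60, 61))
#>   time_iz_target_s time_iz_no_target_s time_corners_s        ir   phenotype
#> 1               82                  60             NA 1.3666667   resilient
#> 2               45                  61             NA 0.7377049 susceptible
```

Cohort-level: `simulate_cohort()` → `cohort_metrics()` → `rm_anova(m,
"commission_rate", gg_correction = TRUE)` tests the day × group
interaction that separates defeated cohorts from controls. For calcium,
`simulate_calcium()` → `correct_drift()` → `zscore_traces()` →
`align_to_cues()` → `detect_modulated()` / `population_median()` /
`heatmap_matrix()`; `plot()` methods draw the median ± MAD trace and the
sorted heat map.

See `vignettes/gonogo-methods.Rmd` for the models, parameter defaults and
numerical choices.

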