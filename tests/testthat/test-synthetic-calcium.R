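test_that("event-free specs reproduce the bleach curve exactly", {
  spec <- calcium_sim_spec(n_neurons = 2, n_frames = 1000,
                           baseline_rate_hz = 0, frac_modulated = 0,
                           noise_sd = 0, bleach_tau_s = 300,
                           baseline_f0 = 1.5, seed = 4)
  sim <- simulate_calcium(spec)
  t_idx <- 0:999
  expected <- 1.5 * exp(-t_idx / (20 * 300))
  expect_equal(sim$trace$values[1, ], expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sim$trace$values[2, ], expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(length(sim$truth$modulated_ids), 0L)
})

test_that("transient counts follow the Poisson oracle", {
  rate <- 0.4; T_s <- 2500
  spec <- calcium_sim_spec(n_neurons = 1, n_frames = T_s * 20,
                           baseline_rate_hz = rate, frac_modulated = 0,
                           noise_sd = 0, seed = 10)
  sim <- simulate_calcium(spec)
  n_events <- length(sim$truth$event_times[[1]])
  expect_lt(abs(n_events - rate * T_s), 3 * sqrt(rate * T_s))
})

test_that("kernel peak amplitude is frame-rate invariant", {
  for (fps in c(10, 20, 40)) {
    k <- gonogo:::.transient_kernel(0.07, 0.7, fps)
    expect_equal(max(k), 1)
    expect_equal(k[1], 0)
    spec <- calcium_sim_spec(n_neurons = 1, n_frames = 200 * fps,
                             frame_rate_hz = fps, baseline_rate_hz = 0.01,
                             frac_modulated = 0, noise_sd = 0,
                             transient_amplitude = 0.8, seed = 6)
    sim <- simulate_calcium(spec)
    ev <- sim$truth$event_times[[1]]
    # isolated events peak at exactly f0 + amplitude
    if (length(ev) >= 1 && all(diff(c(0, ev)) > 10)) {
      expect_equal(max(sim$trace$values[1, ]), 1 + 0.8,
                   tolerance = 1e-9, info = paste("fps", fps))
    }
  }
})

test_that("modulated neurons receive extra cue-locked events", {
  cues <- as.integer(seq(100, by = 600, length.out = 40))
  spec <- calcium_sim_spec(n_neurons = 40, n_frames = 24500,
                           baseline_rate_hz = 0.1, frac_modulated = 0.5,
                           effect_gain = 5, noise_sd = 0,
                           cue_frames = cues, seed = 12)
  sim <- simulate_calcium(spec)
  expect_identical(length(sim$truth$modulated_ids), 20L)
  cue_t <- (cues - 1) / 20
  in_window <- function(times) {
    sum(vapply(times, function(t) any(t > cue_t & t <= cue_t + 10),
               logical(1)))
  }
  n_in <- vapply(sim$truth$event_times, in_window, numeric(1))
  mod <- seq_len(40) %in% sim$truth$modulated_ids
  # windows cover 400 of 1225 s: unmodulated ~ 32% of events inside,
  # modulated ~ 5x rate inside
  expect_gt(mean(n_in[mod]), 2.5 * mean(n_in[!mod]))
})

test_that("rate gain of 1 leaves the modulated set undetectable", {
  cues <- as.integer(seq(100, by = 600, length.out = 40))
  spec <- calcium_sim_spec(n_neurons = 200, n_frames = 24500,
                           baseline_rate_hz = 0.15, frac_modulated = 0.2,
                           effect_gain = 1, cue_frames = cues, seed = 13)
  sim <- simulate_calcium(spec)
  al <- align_to_cues(zscore_traces(sim$trace))
  res <- detect_modulated(al)
  sens <- mean(sim$truth$modulated_ids %in% which(res$modulated))
  expect_lte(sens, 0.05)  # nothing beyond false-positive level
})

test_that("detection sensitivity is monotone in effect gain and trial count", {
  cues <- as.integer(seq(100, by = 600, length.out = 50))
  sens_at_gain <- function(gain, seed) {
    spec <- calcium_sim_spec(n_neurons = 150, n_frames = 30200,
                             frac_modulated = 0.4, effect_gain = gain,
                             cue_frames = cues, seed = seed)
    sim <- simulate_calcium(spec)
    al <- align_to_cues(zscore_traces(sim$trace))
    res <- detect_modulated(al)
    mean(sim$truth$modulated_ids %in% which(res$modulated))
  }
  s_gain <- vapply(c(1.2, 2.5, 5), sens_at_gain, numeric(1), seed = 14)
  expect_true(all(diff(s_gain) >= 0))
  expect_lt(s_gain[1], 0.7)
  expect_gt(s_gain[3], 0.9)

  # trial count: evaluate one simulation on nested cue subsets
  spec <- calcium_sim_spec(n_neurons = 150, n_frames = 30200,
                           frac_modulated = 0.4, effect_gain = 2.2,
                           cue_frames = cues, seed = 15)
  sim <- simulate_calcium(spec)
  z <- zscore_traces(sim$trace)
  sens_at_n <- vapply(c(10, 25, 50), function(n_tr) {
    tr <- z
    tr$cue_events <- z$cue_events[seq_len(n_tr), ]
    res <- detect_modulated(align_to_cues(tr))
    mean(sim$truth$modulated_ids %in% which(res$modulated))
  }, numeric(1))
  expect_true(all(diff(sens_at_n) >= 0))
})

test_that("drift correction then z-scoring equals z-scoring alone on bleach-free traces", {
  spec <- calcium_sim_spec(n_neurons = 3, n_frames = 20000,
                           baseline_rate_hz = 0.02, frac_modulated = 0,
                           noise_sd = 0, bleach_tau_s = 0, seed = 16)
  sim <- simulate_calcium(spec)
  z_direct <- zscore_traces(sim$trace)
  z_via_dff <- zscore_traces(correct_drift(sim$trace))
  expect_lt(max(abs(z_direct$values - z_via_dff$values)), 1e-6)
})

test_that("sim-spec invariants are enforced", {
  expect_error(calcium_sim_spec(frac_modulated = 1.2), "frac_modulated")
  expect_error(calcium_sim_spec(rise_tau_s = 0.8, decay_tau_s = 0.7),
               "rise_tau_s")
  expect_error(calcium_sim_spec(n_frames = 100, cue_frames = 500L),
               "cue_frames")
  expect_error(calcium_sim_spec(noise_sd = -1), "noise_sd")
})
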