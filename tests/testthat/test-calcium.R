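test_that("drift correction yields flat dF/F and preserves fast transients", {
  fps <- 20
  n <- 1800 * fps  # 30-min trace
  t_s <- (seq_len(n) - 1) / fps
  # constant positive trace -> exactly zero dF/F
  flat <- trace_matrix(matrix(2.5, 1, n), fps)
  expect_true(all(correct_drift(flat)$values == 0))

  # exponential bleach, no transients: residual linear trend ~ 0
  bleach <- trace_matrix(matrix(1.5 * exp(-t_s / 600), 1, n), fps)
  d <- correct_drift(bleach)$values[1, ]
  slope_per_min <- unname(stats::coef(stats::lm(d ~ I(t_s / 60)))[2])
  expect_lt(abs(slope_per_min), 1e-3)

  # flat trace with one 2-s boxcar transient: amplitude preserved within 10%
  x <- rep(1, n)
  x[20000:20039] <- 2  # boxcar of height 1 above baseline
  box <- correct_drift(trace_matrix(matrix(x, 1, n), fps))
  amp <- max(box$values[1, ])
  expect_lt(abs(amp - 1), 0.1)

  # non-positive baseline is an actionable error
  neg <- trace_matrix(matrix(seq(-1, 1, length.out = n), 1, n), fps)
  expect_error(correct_drift(neg), "raise")
})

test_that("z-scoring standardizes each neuron and is scale invariant", {
  set.seed(5)
  v <- matrix(stats::rnorm(4 * 5000, mean = 3, sd = 2), 4, 5000)
  z <- zscore_traces(trace_matrix(v, 20))
  expect_true(all(abs(rowMeans(z$values)) < 1e-10))
  expect_true(all(abs(apply(z$values, 1, stats::sd) - 1) < 1e-10))
  z2 <- zscore_traces(trace_matrix(2 * v, 20))
  expect_equal(z$values, z2$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  # normal upper tail: about 2.3% of samples above +2
  expect_lt(abs(mean(z$values > 2) - stats::pnorm(2, lower.tail = FALSE)),
            0.003)
  # zero-variance neuron excluded with warning, not NaN
  v[2, ] <- 7
  expect_warning(zz <- zscore_traces(trace_matrix(v, 20)),
                 "zero-variance")
  expect_identical(nrow(zz$values), 3L)
  expect_true(all(is.finite(zz$values)))
})

test_that("peri-cue alignment arithmetic is exact", {
  fps <- 20
  n <- 4000
  cues <- data.frame(frame_index = c(10, 500, 1500, 3950),
                     trial_type = c("go", "go", "nogo", "go"),
                     outcome = c("hit", "hit", "correct_rejection", "hit"),
                     day = 1L)
  v <- matrix(0, 2, n)
  # plant a single-frame pulse 1 s after the two usable cues
  v[1, 500 + 20] <- 5
  v[1, 1500 + 20] <- 5
  tr <- trace_matrix(v, fps, cues)
  expect_warning(al <- align_to_cues(tr, pre_s = 3, post_s = 10),
                 "2 cue")  # frames 10 and 3950 cannot host a full window
  expect_identical(dim(al$z), c(2L, 2L, 261L))
  expect_identical(al$onset_index, 61L)
  expect_equal(al$time_s[61], 0)
  expect_identical(al$n_dropped, 2L)
  mean_tc <- colMeans(al$z[1, , ])
  expect_identical(which.max(mean_tc), 81L)  # +1 s at 20 fps
  expect_equal(al$time_s[81], 1)
  # no usable cue at all -> explicit error
  tr_bad <- trace_matrix(v, fps, cues[c(1, 4), ])
  expect_error(suppressWarnings(align_to_cues(tr_bad)), "no cue has")
})

test_that("population median/MAD behave on degenerate and split inputs", {
  time_s <- seq(-1, 2, by = 0.25)
  zeros <- toy_tensor(array(0, c(3, 4, length(time_s))), time_s)
  pm <- population_median(zeros)
  expect_true(all(pm$median == 0) && all(pm$mad == 0))

  go_only <- zeros
  go_only$trials$trial_type <- "go"
  pm_split <- population_median(go_only, split_by = "trial_type")
  expect_identical(unique(pm_split$level), "go")  # no empty nogo level

  # median/MAD equal direct computation on a random tensor
  set.seed(3)
  z <- array(stats::rnorm(5 * 6 * length(time_s)), c(5, 6, length(time_s)))
  tens <- toy_tensor(z, time_s)
  pm2 <- population_median(tens)
  k <- 7
  expect_equal(pm2$median[k], stats::median(z[, , k]))
  expect_equal(pm2$mad[k],
               stats::median(abs(z[, , k] - stats::median(z[, , k]))))
})

test_that("align -> median pipeline is equivariant to neuron and trial permutation", {
  set.seed(11)
  fps <- 20
  n <- 3000
  v <- matrix(stats::rnorm(6 * n), 6, n)
  cues <- data.frame(frame_index = c(300, 900, 1600, 2300),
                     trial_type = "go", outcome = "hit", day = 1L)
  al <- align_to_cues(trace_matrix(v, fps, cues))
  pm <- population_median(al)
  v_perm <- v[c(4, 1, 6, 2, 5, 3), ]
  al_p <- align_to_cues(trace_matrix(v_perm, fps, cues))
  expect_equal(population_median(al_p)$median, pm$median)
  cues_perm <- cues[c(3, 1, 4, 2), ]
  al_t <- align_to_cues(trace_matrix(v, fps, cues_perm))
  expect_equal(population_median(al_t)$median, pm$median)
})

test_that("rank-sum screen matches exact enumeration for small trial counts", {
  set.seed(21)
  time_s <- seq(-3, 10, by = 0.5)
  for (n_tr in c(2, 3, 5, 8)) {
    for (rep in 1:5) {
      z <- array(stats::rnorm(1 * n_tr * length(time_s)),
                 c(1, n_tr, length(time_s)))
      tens <- toy_tensor(z, time_s)
      res <- detect_modulated(tens, cutoff = 1e-4)
      M <- z[1, , , drop = FALSE][1, , ]
      if (n_tr == 2) M <- matrix(M, nrow = n_tr)
      pre_m <- rowMeans(M[, time_s < 0, drop = FALSE])
      post_m <- rowMeans(M[, time_s >= 0, drop = FALSE])
      expect_equal(res$p_value, exact_ranksum_p(post_m, pre_m),
                   tolerance = 1e-12,
                   info = sprintf("n_tr=%d rep=%d", n_tr, rep))
    }
  }
})

test_that("rank-sum screen flags extreme separation and not identical data", {
  time_s <- seq(-3, 10, by = 1 / 20)
  n_tr <- 50
  z <- array(0, c(2, n_tr, length(time_s)))
  # neuron 1: every post mean strictly above every pre mean
  set.seed(2)
  z[1, , time_s < 0] <- stats::rnorm(n_tr * sum(time_s < 0), 0, 0.1)
  z[1, , time_s >= 0] <- stats::rnorm(n_tr * sum(time_s >= 0), 5, 0.1)
  # neuron 2: identical pre and post
  tens <- toy_tensor(z, time_s)
  res <- detect_modulated(tens)
  expect_lt(res$p_value[1], 1e-4)
  expect_true(res$modulated[1])
  expect_identical(res$direction[1], "up")
  expect_equal(res$p_value[2], 1)
  expect_false(res$modulated[2])
  expect_error(detect_modulated(toy_tensor(z[, 1, , drop = FALSE], time_s)),
               ">= 2 trials")
})

test_that("heat-map rows are normalized to [-1, 1] and sorted by peak latency", {
  time_s <- seq(-3, 10, by = 1 / 20)
  n_s <- length(time_s)
  z <- array(0, c(3, 4, n_s))
  peak_at <- function(t_peak, amp) {
    amp * exp(-(time_s - t_peak)^2 / 0.5)
  }
  for (tr in 1:4) {
    z[1, tr, ] <- peak_at(5, 2)   # late responder
    z[2, tr, ] <- peak_at(1, 0.5) # early responder
    # neuron 3 stays zero
  }
  hm <- heatmap_matrix(toy_tensor(z, time_s), neurons = 1:3)
  expect_true(all(hm >= -1 & hm <= 1))
  nonzero <- rowSums(abs(hm)) > 0
  expect_true(all(abs(apply(abs(hm[nonzero, ]), 1, max) - 1) < 1e-12))
  # early peak sorts first
  lat <- attr(hm, "peak_latency_s")
  expect_equal(lat[1], 1, tolerance = 0.06)
  expect_equal(lat[2], 5, tolerance = 0.06)
  expect_true(any(attr(hm, "zero_rows")))
  expect_error(heatmap_matrix(toy_tensor(z, time_s), neurons = integer(0)),
               "no neurons")
})

test_that("synchronized responses give tighter peak latencies than desynchronized", {
  set.seed(9)
  time_s <- seq(-3, 10, by = 1 / 20)
  n_s <- length(time_s)
  mk <- function(peaks) {
    z <- array(stats::rnorm(10 * 6 * n_s, 0, 0.05), c(10, 6, n_s))
    for (i in 1:10) {
      for (tr in 1:6) {
        z[i, tr, ] <- z[i, tr, ] + exp(-(time_s - peaks[i])^2 / 0.3)
      }
    }
    toy_tensor(z, time_s)
  }
  sync <- heatmap_matrix(mk(rep(1.5, 10)), neurons = 1:10)
  desync <- heatmap_matrix(mk(seq(0.5, 9, length.out = 10)), neurons = 1:10)
  expect_lt(stats::sd(attr(sync, "peak_latency_s")),
            stats::sd(attr(desync, "peak_latency_s")))
})
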