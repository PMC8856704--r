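test_that("degenerate policies force the corresponding outcomes", {
  cfg <- task_config(stage = 4, session_duration_s = 600, seed = 1)
  pol <- agent_policy(p_respond_go = 1, p_respond_nogo = 0,
                      premature_hazard_per_s = 0, learn_rate_go = 0,
                      learn_rate_nogo = 0, p_respond_go_ceiling = 1,
                      p_respond_nogo_floor = 0, seed = 2)
  tr <- attr(simulate_day(pol, cfg, day = 1), "trials")
  expect_true(all(tr$outcome[tr$trial_type == "go"] == "hit"))
  expect_true(all(tr$outcome[tr$trial_type == "nogo"] ==
                    "correct_rejection"))
  expect_true(all(tr$n_premature_restarts == 0L))

  pol0 <- agent_policy(p_respond_go = 0, p_respond_nogo = 0,
                       premature_hazard_per_s = 0, learn_rate_go = 0,
                       learn_rate_nogo = 0, p_respond_nogo_floor = 0,
                       seed = 2)
  cfg_cr_off <- task_config(stage = 4, session_duration_s = 600,
                            reward_on_correct_rejection = FALSE, seed = 1)
  log0 <- simulate_day(pol0, cfg_cr_off, day = 1)
  expect_identical(sum(log0$kind == "reward"), 0L)
})

test_that("premature pokes follow the configured Poisson hazard", {
  # non-responding agent, fixed hazard; compare the premature count with
  # the Poisson expectation over the actual time spent in ITIs
  cfg <- task_config(stage = 4, session_duration_s = 13000, iti_min_s = 10,
                     iti_max_s = 10, limited_hold_s = 3, p_nogo = 0,
                     seed = 3)
  pol <- agent_policy(p_respond_go = 0, p_respond_nogo = 0,
                      premature_hazard_per_s = 0.5, learn_rate_go = 0,
                      learn_rate_nogo = 0, p_respond_nogo_floor = 0,
                      seed = 5)
  log <- simulate_day(pol, cfg, day = 1)
  ev <- as.data.frame(log)
  # ITI time = from each iti_start to the next cue-on / restart / session end
  starts <- which(ev$kind == "iti_start")
  cand <- which(ev$kind %in% c("cue_go_on", "cue_nogo_on", "poke",
                               "session_end"))
  nxt <- cand[findInterval(starts, cand) + 1L]
  t_iti <- sum(ev$time_s[nxt] - ev$time_s[starts])
  expect_gt(t_iti, 1e4)
  n_prem <- sum(ev$kind == "trial_restart")
  expected <- 0.5 * t_iti
  expect_lt(abs(n_prem - expected), 3 * sqrt(expected))
})

test_that("learning curves move response probabilities monotonically", {
  pol <- agent_policy()
  days <- 1:14
  p <- vapply(days, function(d) unlist(policy_on_day(pol, d)), numeric(2))
  expect_true(all(diff(p["p_nogo", ]) <= 0))   # commission propensity falls
  expect_true(all(diff(p["p_go", ]) >= 0))     # go responding rises
  expect_true(all(p >= 0 & p <= 1))
  # defeated template decays slower on the no-go side only
  def <- agent_policy(group = "defeated", learn_rate_nogo = 0.10)
  p_def <- vapply(days, function(d) unlist(policy_on_day(def, d)),
                  numeric(2))
  expect_true(all(p_def["p_nogo", -1] > p["p_nogo", -1]))
  expect_equal(p_def["p_go", ], p["p_go", ])
})

test_that("simulated commission rates recover the policy decay direction", {
  cfg <- task_config(stage = 4, session_duration_s = 600, seed = 1)
  spec <- cohort_spec(n_per_group = 4, n_days = 8, base_seed = 77)
  m <- cohort_metrics(simulate_cohort(spec, cfg))
  slope_of <- function(g) {
    d <- m[m$group == g, ]
    unname(stats::coef(stats::lm(commission_rate ~ day, d))["day"])
  }
  expect_lt(slope_of("control"), 0)
  expect_lt(slope_of("defeated"), 0)
  # slower learner -> shallower decay
  expect_gt(slope_of("defeated"), slope_of("control"))
})

test_that("cohort simulation is reproducible and seed-isolated", {
  cfg <- task_config(stage = 4, session_duration_s = 180, seed = 1)
  spec <- cohort_spec(n_per_group = 2, n_days = 2, base_seed = 11)
  c1 <- simulate_cohort(spec, cfg)
  c2 <- simulate_cohort(spec, cfg)
  expect_identical(lapply(c1$logs, as.data.frame),
                   lapply(c2$logs, as.data.frame))
  expect_identical(c1$truth, c2$truth)
  expect_identical(length(c1$logs), 2L * 2L * 2L)

  # changing one subject's seed changes only that subject's sessions
  pol_a <- agent_policy(seed = 100)
  pol_b <- agent_policy(seed = 101)
  la <- simulate_day(pol_a, cfg, day = 1)
  lb <- simulate_day(pol_b, cfg, day = 1)
  la2 <- simulate_day(pol_a, cfg, day = 1)
  expect_identical(as.data.frame(la), as.data.frame(la2))
  expect_false(identical(as.data.frame(la), as.data.frame(lb)))
})

test_that("cohort truth table records the effective per-day parameters", {
  cfg <- task_config(stage = 4, session_duration_s = 120, seed = 1)
  spec <- cohort_spec(n_per_group = 2, n_days = 3, base_seed = 5)
  ch <- simulate_cohort(spec, cfg)
  expect_identical(nrow(ch$truth), 12L)
  row <- ch$truth[ch$truth$group == "defeated" & ch$truth$day == 3, ][1, ]
  expect_equal(row$p_nogo_effective,
               policy_on_day(spec$defeated, 3)$p_nogo)
})
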