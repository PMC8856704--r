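test_that("scripted sessions reproduce hand-derived transcripts exactly", {
  for (name in names(scripted_scenarios())) {
    sc <- scripted_scenarios()[[name]]
    log <- run_session(sc$config, sc$pokes)
    expect_equal(strip_log(log), sc$expected, info = name)
  }
})

test_that("config validation names the offending field", {
  expect_error(task_config(iti_min_s = -1), "iti_min_s")
  expect_error(task_config(iti_min_s = 5, iti_max_s = 3), "iti_min_s")
  expect_error(task_config(p_nogo = 1.5), "p_nogo")
  expect_error(task_config(stage = 7), "stage")
  expect_error(task_config(limited_hold_s = 0), "limited_hold_s")
})

test_that("session start obeys stage semantics", {
  s4 <- start_session(task_config(stage = 4, seed = 3))
  ev4 <- session_events(s4)
  expect_identical(ev4$kind[1:2], c("session_start", "iti_start"))
  expect_identical(ev4$time_s[1:2], c(0, 0))

  s0 <- start_session(task_config(stage = 0, seed = 3))
  ev0 <- session_events(s0)
  expect_identical(ev0$kind[1:2], c("session_start", "cue_go_on"))
})

test_that("step_session rejects out-of-order pokes and times", {
  st <- start_session(task_config(stage = 4, seed = 1))
  st <- step_session(st, until_s = 10)
  expect_error(step_session(st, until_s = 5), "ordering")
  expect_error(step_session(st, poke = 9, until_s = 20), "ordering")
  expect_error(run_session(task_config(seed = 1), pokes = c(5, 3)),
               "ordering")
})

test_that("identical config, seed and schedule give identical event logs", {
  cfg <- task_config(stage = 4, session_duration_s = 300, seed = 99)
  pokes <- c(3.2, 40, 41, 100.5, 250)
  a <- run_session(cfg, pokes)
  b <- run_session(cfg, pokes)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "trials"), attr(b, "trials"))
  # and serialized byte-identity
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_event_log(a, fa); write_event_log(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("empty poke schedules force the outcome dictated by trial type", {
  cfg <- task_config(stage = 4, session_duration_s = 1800, p_nogo = 0,
                     seed = 5)
  log <- run_session(cfg)
  tr <- attr(log, "trials")
  expect_true(all(tr$outcome == "omission"))
  expect_identical(sum(log$kind == "reward"), 0L)

  cfg1 <- task_config(stage = 4, session_duration_s = 1800, p_nogo = 1,
                      seed = 5)
  log1 <- run_session(cfg1)
  tr1 <- attr(log1, "trials")
  expect_true(all(tr1$outcome == "correct_rejection"))
  # one reward per completed correct rejection, none otherwise
  expect_identical(sum(log1$kind == "reward"), nrow(tr1))
})

test_that("rewards only follow hits, rewarded correct rejections or stage-0 pokes", {
  cfg <- task_config(stage = 4, session_duration_s = 900, seed = 17)
  pol <- agent_policy(seed = 4)
  log <- simulate_day(pol, cfg, day = 2)
  kinds <- log$kind
  prev <- kinds[which(kinds == "reward") - 1L]
  expect_true(all(prev %in% c("cue_off", "poke")))
  tr <- attr(log, "trials")
  n_rewarded <- sum(tr$outcome %in% c("hit", "correct_rejection"))
  expect_identical(sum(kinds == "reward"), n_rewarded)
})

test_that("event times never exceed the session duration", {
  cfg <- task_config(stage = 4, session_duration_s = 200, seed = 2)
  log <- simulate_day(agent_policy(seed = 8), cfg, day = 1)
  expect_true(all(log$time_s <= cfg$session_duration_s))
  expect_identical(log$kind[nrow(log)], "session_end")
  expect_identical(sum(log$kind == "session_end"), 1L)
})

test_that("ITI draws are uniform on [iti_min, iti_max]", {
  # >= 1e4 draws through the engine itself; KS test at alpha = 0.01
  cfg <- task_config(stage = 4, session_duration_s = 65000, iti_min_s = 3,
                     iti_max_s = 9, limited_hold_s = 0.1, p_nogo = 0,
                     seed = 31)
  log <- run_session(cfg)
  t_iti <- log$time_s[log$kind == "iti_start"]
  t_cue <- log$time_s[log$kind == "cue_go_on"]
  draws <- t_cue - t_iti[seq_along(t_cue)]
  expect_gt(length(draws), 1e4)
  expect_true(all(draws >= 3 & draws <= 9))
  ks <- suppressWarnings(stats::ks.test(draws, "punif", 3, 9))
  expect_gt(ks$p.value, 0.01)
})

test_that("step-wise and batch drivers agree", {
  cfg <- task_config(stage = 4, session_duration_s = 60, seed = 12)
  pokes <- c(4, 18.5, 33)
  batch <- run_session(cfg, pokes)
  st <- start_session(cfg)
  for (p in pokes) st <- step_session(st, poke = p, until_s = p)
  st <- step_session(st, until_s = 60)
  expect_identical(strip_log(session_events(st)), strip_log(batch))
})
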