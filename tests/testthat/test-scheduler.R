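step_seq <- function(times, config = scheduler_config(sham_probability = 0),
                     gate = TRUE, alarms = rep(FALSE, length(times))) {
  st <- new_scheduler_state()
  evs <- list()
  for (i in seq_along(times)) {
    r <- scheduler_step(times[i], crossing = !alarms[i], gate_allow = gate,
                        post_stim_alarm = alarms[i], state = st, config = config)
    st <- r$state
    if (!is.null(r$event)) evs[[length(evs) + 1]] <- r$event
  }
  if (length(evs)) dplyr::bind_rows(evs) else NULL
}

test_that("pacing: two pulses per train, then at least 9 s of silence", {
  # crossings at 0, 1, then 5 s after the pair: third must be suppressed
  ev <- step_seq(c(0, 1, 6))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$pulse_index, c(1L, 2L))
  # a crossing 9 s after the pair starts a new train
  ev2 <- step_seq(c(0, 1, 10.1))
  expect_equal(nrow(ev2), 3)
  expect_equal(ev2$train_index, c(1L, 1L, 2L))
  # second pulse must come within the 3-s window of the first; after the
  # timeout the train closes and the 9-s gap still applies from its pulse
  ev3 <- step_seq(c(0, 4, 20))
  expect_equal(ev3$time_s, c(0, 20))
  expect_equal(ev3$pulse_index, c(1L, 1L))
  expect_equal(ev3$train_index, 1:2)
})

test_that("gate and alarms suppress stimulation", {
  expect_null(step_seq(c(0, 1, 2), gate = FALSE))
  # alarm at 2 s starts a 30-s pause: crossings before 32 s are ignored
  ev <- step_seq(c(0, 1, 2, 15, 31.9, 32.5),
                 alarms = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(nrow(ev), 3)
  expect_equal(ev$time_s, c(0, 1, 32.5))
  expect_error(step_seq(c(5, 4)), "non-decreasing")
})

test_that("sham randomization is per train and honours the probability", {
  cfg0 <- scheduler_config(sham_probability = 0)
  times <- as.vector(rbind(seq(0, by = 12, length.out = 600),
                           seq(1, by = 12, length.out = 600)))
  set.seed(1)
  ev0 <- step_seq(times, cfg0)
  expect_true(all(ev0$arm == "stim"))
  cfg5 <- scheduler_config(sham_probability = 0.5)
  set.seed(42)
  ev5 <- step_seq(times, cfg5)
  expect_gte(nrow(ev5), 1000)
  # both pulses of a train share the arm
  arms <- tapply(ev5$arm, ev5$train_index, function(a) length(unique(a)))
  expect_true(all(arms == 1))
  # 600 trains at p = 0.5: binomial 99% interval
  expect_gt(mean(ev5$arm == "sham"), 0.44)
  expect_lt(mean(ev5$arm == "sham"), 0.56)
})

test_that("closed-loop runs are deterministic and rule-compliant", {
  qm <- tiny_quality_model(); nm <- tiny_n3_model()
  cfg <- sleep_sim_config(duration_s = 3600, seed = 321)
  sim <- synthesize_night(simulate_hypnogram(cfg), cfg)
  res1 <- run_closed_loop(sim$recording, qm, nm, seed = 5)
  res2 <- run_closed_loop(sim$recording, qm, nm, seed = 5)
  expect_identical(res1$events, res2$events)
  expect_gt(nrow(res1$events), 0)
  # all inter-train gaps >= 9 s, checked exhaustively over the log
  trains <- dplyr::summarise(dplyr::group_by(res1$events, train_index),
                             first = min(time_s), last = max(time_s),
                             .groups = "drop")
  if (nrow(trains) > 1)
    expect_true(all(diff(trains$first) - (trains$last[-nrow(trains)] - trains$first[-nrow(trains)]) >= 9))
  expect_equal(nrow(audit_stim_log(res1$events, res1$predicted, res1$movements)), 0)
  # no pulse outside gate-allowed epochs' span
  first_n3 <- res1$predicted$onset_s[which(res1$predicted$is_n3)[1]] + 30
  if (nrow(res1$events))
    expect_true(all(res1$events$time_s >= first_n3 + 900))
  # sham-only configuration yields no stim arms
  res3 <- run_closed_loop(sim$recording, qm, nm,
                          config = scheduler_config(sham_probability = 1), seed = 5)
  expect_true(all(res3$events$arm == "sham"))
})

test_that("a wake-only night never opens the gate", {
  qm <- tiny_quality_model(); nm <- tiny_n3_model()
  cfg <- sleep_sim_config(duration_s = 1800, seed = 66)
  sim <- synthesize_night(hypnogram(rep("W", 60)), cfg)
  res <- run_closed_loop(sim$recording, qm, nm, seed = 2)
  expect_equal(nrow(res$events), 0)
})
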