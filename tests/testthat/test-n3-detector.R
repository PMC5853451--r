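test_that("relative band powers isolate pure tones and sum to one", {
  fs <- 250; t <- (0:7499) / fs
  f2 <- extract_sleep_features(sin(2 * pi * 2 * t) * 50, fs = fs)
  expect_gte(f2$rel_power_0p4_4, 0.95)
  f10 <- extract_sleep_features(sin(2 * pi * 10 * t) * 50, fs = fs)
  expect_gte(f10$rel_power_8_12, 0.95)
  night <- unit_night()
  for (e in c(2, 30, 60)) {
    fe <- extract_sleep_features(night$recording$eeg[((e - 1) * 7500 + 1):(e * 7500), 1],
                                 fs = fs)
    expect_equal(fe$rel_power_0p4_4 + fe$rel_power_4_8 + fe$rel_power_8_12 +
                   fe$rel_power_12_18, 1, tolerance = 1e-6)
  }
})

test_that("permutation entropy: degenerate and noise extremes", {
  expect_equal(permutation_entropy(seq_len(1000)), 0)
  expect_equal(permutation_entropy(rep(1, 1000)), 0)
  set.seed(11)
  x <- runif(20000)
  pe <- permutation_entropy(x, order = 3, delay = 1)
  expect_gte(pe, 0.99)
  # brute-force pattern counting on the same draw
  pats <- vapply(seq_len(length(x) - 2), function(i)
    paste(order(x[i:(i + 2)]), collapse = ""), "")
  p <- table(pats) / length(pats)
  expect_equal(pe, -sum(p * log(p)) / log(6), tolerance = 1e-10)
  expect_error(permutation_entropy(1:3, order = 4, delay = 2), "short")
})

test_that("spindle detector counts injected bursts and ignores the floor", {
  fs <- 250; n <- 30 * fs; t <- (0:(n - 1)) / fs
  set.seed(5)
  noise <- as.numeric(stats::filter(rnorm(n, sd = 12), rep(1 / 3, 3), sides = 2))
  noise[is.na(noise)] <- 0
  burst <- function(t0, dur = 1, f = 13, amp = 40) {
    w <- numeric(n); i <- which(t >= t0 & t < t0 + dur)
    w[i] <- amp * sin(2 * pi * f * (t[i] - t0)) * socloop:::hann_win(length(i))
    w
  }
  one <- noise + burst(10)
  expect_equal(nrow(detect_spindles(one, fs)), 1)
  expect_equal(nrow(detect_spindles(noise, fs, k = 3)), 0)
  two <- noise + burst(8) + burst(14)
  expect_equal(nrow(detect_spindles(two, fs)), 2)
})

test_that("slow-oscillation detector matches injected events", {
  fs <- 250; n <- 30 * fs; t <- (0:(n - 1)) / fs
  x <- rnorm(n, sd = 5)
  onsets <- c(4, 12, 21)
  for (t0 in onsets) {
    i <- which(t >= t0 & t < t0 + 1)
    x[i] <- x[i] + 90 * sin(2 * pi * 1 * (t[i] - t0))
  }
  ev <- detect_slow_oscillations(x, fs)
  expect_equal(nrow(ev), 3)
  expect_true(all(abs(ev$onset_s - onsets) < 0.2))
  expect_equal(nrow(detect_slow_oscillations(rep(0, n), fs)), 0)
  # stricter amplitude criterion never finds more events
  expect_lte(nrow(detect_slow_oscillations(x, fs, amp_uv = 150)), nrow(ev))
})

test_that("unscorable epochs are flagged and never classified N3", {
  x <- rnorm(7500, sd = 20)
  x[1:4000] <- NA
  fe <- extract_sleep_features(x, fs = 250)
  expect_true(fe$unscorable)
  expect_equal(predict_n3(fe, tiny_n3_model()), 0)
})

test_that("N3 probability ranks simulated N3 epochs above wake", {
  nm <- tiny_n3_model()
  expect_s3_class(nm, "n3_model")
  qm <- tiny_quality_model()
  cfg <- sleep_sim_config(duration_s = 3600, seed = 888)
  hyp <- simulate_hypnogram(cfg)
  sim <- synthesize_night(hyp, cfg)
  vc <- gate_and_select(sim$recording, qm)
  fe <- epoch_features_for_night(vc, sim$recording$accel)
  p <- predict_n3(fe, nm)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean(p[hyp$stage == "N3"]), mean(p[hyp$stage == "W"]))
  # threshold sweep gives a monotone ROC with high AUC
  lab <- hyp$stage == "N3"
  auc <- mean(outer(p[lab], p[!lab], ">")) + 0.5 * mean(outer(p[lab], p[!lab], "=="))
  expect_gte(auc, 0.9)
})

test_that("hard conditions enforce onset delay, lockout and cutoff", {
  st <- new_gate_state()
  r <- hard_conditions(st, 1000, TRUE)        # first N3 detected at t = 1000
  expect_false(r$allow)
  expect_false(hard_conditions(r$state, 1000 + 600, TRUE)$allow)   # wait 15 min
  expect_true(hard_conditions(r$state, 1000 + 900, TRUE)$allow)
  expect_false(hard_conditions(r$state, 1000 + 900, FALSE)$allow)  # not N3
  # movement less than 3 min ago blocks
  st2 <- note_movement(r$state, 2000)
  expect_false(hard_conditions(st2, 2000 + 120, TRUE)$allow)
  expect_true(hard_conditions(st2, 2000 + 180, TRUE)$allow)
  # hard stop 4 h after the first N3
  expect_true(hard_conditions(r$state, 1000 + 14400, TRUE)$allow)
  expect_false(hard_conditions(r$state, 1000 + 14401, TRUE)$allow)
  expect_error(hard_conditions(r$state, 999, TRUE), "non-decreasing")
})
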