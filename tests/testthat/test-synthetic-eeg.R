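test_that("hypnogram has one epoch per 30 s and is deterministic per seed", {
  cfg <- sleep_sim_config(duration_s = 3600, seed = 9)
  h <- simulate_hypnogram(cfg)
  expect_equal(nrow(h), 120)
  expect_true(all(h$stage %in% c("W", "N1", "N2", "N3", "REM")))
  expect_identical(h, simulate_hypnogram(cfg))
  expect_error(simulate_hypnogram(sleep_sim_config(duration_s = 10)), "epoch")
})

test_that("default 8-h nights have plausible N3 structure across seeds", {
  frac <- vapply(1:200, function(s)
    mean(simulate_hypnogram(sleep_sim_config(seed = s))$stage == "N3"),
    numeric(1))
  expect_true(all(frac >= 0.10 & frac <= 0.35))
  # at least one contiguous N3 block of >= 20 min
  for (s in c(1, 17, 91)) {
    r <- rle(simulate_hypnogram(sleep_sim_config(seed = s))$stage)
    expect_gte(max(r$lengths[r$values == "N3"]), 40)
  }
})

test_that("stage spectra differ as intended (periodogram oracle)", {
  cfg <- sleep_sim_config(duration_s = 600, seed = 3,
                          artifact_prob_per_epoch = 0, movement_rate_per_hour = 0)
  n3 <- synthesize_night(hypnogram(rep("N3", 20)), cfg)
  w <- synthesize_night(hypnogram(rep("W", 20)), cfg)
  d_n3 <- mean(vapply(1:20, function(e)
    oracle_band_fraction(n3$recording$eeg[((e - 1) * 7500 + 1):(e * 7500), 1],
                         250, c(0.4, 4)), numeric(1)))
  d_w <- mean(vapply(1:20, function(e)
    oracle_band_fraction(w$recording$eeg[((e - 1) * 7500 + 1):(e * 7500), 1],
                         250, c(0.4, 4)), numeric(1)))
  expect_gt(d_n3, d_w)
  alpha_w <- oracle_band_fraction(w$recording$eeg[, 1], 250, c(8, 12))
  alpha_n3 <- oracle_band_fraction(n3$recording$eeg[, 1], 250, c(8, 12))
  expect_gt(alpha_w, alpha_n3)
})

test_that("ground truth logs artifacts and slow-oscillation phase correctly", {
  cfg0 <- sleep_sim_config(duration_s = 600, seed = 5, artifact_prob_per_epoch = 0)
  sim0 <- synthesize_night(hypnogram(rep("N2", 20)), cfg0)
  expect_equal(nrow(sim0$truth$artifact_intervals), 0)

  # noiseless all-N3: the signal is exactly the logged SO events
  cfgp <- sleep_sim_config(duration_s = 600, seed = 6, noise_uv = 0,
                           artifact_prob_per_epoch = 0, movement_rate_per_hour = 0,
                           spindle_rate_per_min = 0)
  simp <- synthesize_night(hypnogram(rep("N3", 20)), cfgp)
  ev <- simp$truth$so_events
  expect_gt(nrow(ev), 50)
  # true phase at the up-state peak (quarter period into the event) is 90
  tpk <- ev$time_s[3] + 0.25 * ev$duration_s[3]
  expect_equal(so_true_phase(simp$truth, tpk), 90, tolerance = 1e-6)
  i <- round(tpk * 250) + 1
  expect_equal(simp$recording$eeg[i, 1], ev$amplitude_uv[3], tolerance = 0.05 * ev$amplitude_uv[3])
  expect_true(is.na(so_true_phase(simp$truth, ev$time_s[3] - 0.05)))

  # Hilbert phase of the noiseless slow-oscillation signal matches the
  # recorded ground-truth phase to within 5 degrees (circular)
  k <- seq_len(min(nrow(ev), 60))
  mid <- c(ev$time_s[k] + 0.25 * ev$duration_s[k],
           ev$time_s[k] + 0.50 * ev$duration_s[k],
           ev$time_s[k] + 0.75 * ev$duration_s[k])
  d <- apply_zero_phase(simp$recording$eeg[, 1], 250, c(0.4, 4), 2)
  hp <- instantaneous_phase(d)[round(mid * 250) + 1]
  err <- abs(circ_diff_deg(hp, so_true_phase(simp$truth, mid)))
  expect_lt(median(err), 5)
})

test_that("movements produce co-timed accelerometer bursts", {
  cfg <- sleep_sim_config(duration_s = 1800, seed = 8, movement_rate_per_hour = 20)
  sim <- synthesize_night(simulate_hypnogram(cfg), cfg)
  mv <- sim$truth$movement_times
  expect_gt(nrow(mv), 2)
  det <- detect_movements(sim$recording$accel, 50)
  # most injected movements are recovered by the magnitude criterion
  hit <- vapply(mv$time_s, function(t) any(abs(det$time_s - t) < 2), logical(1))
  expect_gt(mean(hit), 0.7)
})

test_that("bandpower-threshold oracle separates N3 from the rest", {
  night <- unit_night()
  h <- night$hypnogram
  d <- vapply(seq_len(nrow(h)), function(e)
    oracle_band_fraction(night$recording$eeg[((e - 1) * 7500 + 1):(e * 7500), 1],
                         250, c(0.4, 4)), numeric(1))
  lab <- h$stage == "N3"
  acc <- vapply(sort(d), function(th) mean((d >= th) == lab), numeric(1))
  expect_gt(max(acc), 0.8)
})

test_that("clock drift follows the closed-form lag and rejects bad ratios", {
  cfg <- sleep_sim_config(duration_s = 3600, seed = 2)
  sim <- synthesize_night(simulate_hypnogram(cfg), cfg)
  same <- apply_clock_drift(sim$recording, 0, 1)
  expect_equal(same$eeg[, 1], sim$recording$eeg[, 1], tolerance = 1e-9)

  dr <- apply_clock_drift(sim$recording, 2, 1.0001)
  w <- attr(dr, "drift")
  # lag(t) = offset + (ratio - 1) t; at t = 3600 that is 2.36 s
  expect_equal(tail(w$knots_w, 1) - tail(w$knots_t, 1), 2 + 1e-4 * 3600,
               tolerance = 1e-9)
  # a drifted sample equals the original at the warped time
  i <- 500000
  t_i <- (i - 1) / 250
  orig_t <- 2 + 1.0001 * t_i
  expect_equal(dr$eeg[i, 1],
               approx((seq_len(nrow(sim$recording$eeg)) - 1) / 250,
                      sim$recording$eeg[, 1], orig_t)$y,
               tolerance = 1e-9)
  expect_error(apply_clock_drift(sim$recording, 0, 1.02), "ratio")
})

test_that("the 8-h warp reaches the documented terminal lag", {
  cfg <- sleep_sim_config(duration_s = 8 * 3600, fs_eeg = 40, fs_accel = 10, seed = 4)
  sim <- synthesize_night(simulate_hypnogram(cfg), cfg)
  dr <- attr(apply_clock_drift(sim$recording, 2, 1.0001), "drift")
  expect_equal(tail(dr$knots_w, 1) - tail(dr$knots_t, 1), 4.88, tolerance = 1e-6)
})
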