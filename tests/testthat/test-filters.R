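test_that("acquisition cascade has the four specified stages at 250 Hz", {
  casc <- build_acquisition_cascade(250)
  expect_equal(nrow(casc$stages), 4)
  expect_equal(casc$stages$family, c("butterworth", "butterworth", "butterworth", "bessel"))
  expect_equal(casc$stages$kind, c("bandpass", "bandstop", "bandstop", "bandstop"))
  expect_equal(casc$stages$order, c(4L, 6L, 6L, 2L))
  expect_equal(casc$stages$f_lo, c(0.4, 58, 48, 62))
  expect_equal(casc$stages$f_hi, c(18, 62, 52, 63))
  expect_true(cascade_is_stable(casc))
})

test_that("low sampling rates are handled: drop rule and hard error", {
  # at 128 Hz all stop bands are still below Nyquist (64 Hz): kept, stable
  casc <- build_acquisition_cascade(128)
  expect_true(cascade_is_stable(casc))
  expect_true(all(is.finite(apply_causal(casc, rnorm(2000)))))
  # at 100 Hz the 58-62 and 62-63 stop bands reach/exceed Nyquist (50 Hz)
  expect_warning(c100 <- build_acquisition_cascade(100), "dropping")
  expect_false(any(c100$stages$f_hi >= 50))
  expect_true(cascade_is_stable(c100))
  expect_error(build_acquisition_cascade(30), "36")
})

test_that("causal cascade is stateful (not idempotent) and kills DC", {
  casc <- build_acquisition_cascade(250)
  x <- sin(2 * pi * 5 * (0:4999) / 250)
  once <- apply_causal(casc, x)
  twice <- apply_causal(casc, once)
  expect_gt(max(abs(once - twice)), 0.01)
  dc <- apply_causal(casc, rep(3, 250 * 30))
  expect_lt(max(abs(tail(dc, 250))), 0.05)
})

test_that("steady-state gains match the designed frequency response", {
  casc <- build_acquisition_cascade(250)
  steady_gain <- function(f) {
    x <- sin(2 * pi * f * (0:(250 * 40 - 1)) / 250)
    y <- apply_causal(casc, x)
    # last 10 s, past the transient
    max(abs(tail(y, 2500)))
  }
  h10 <- Mod(cascade_freq_response(casc, 10))
  g10 <- steady_gain(10)
  expect_equal(g10, h10, tolerance = 0.02)
  expect_lt(abs(g10 - 1), 0.10)              # 10 Hz passes within 10%
  g50 <- steady_gain(50)
  expect_lt(20 * log10(g50), -30)            # 50 Hz line removed by >= 30 dB
  expect_lt(20 * log10(steady_gain(60)), -30)
})

test_that("chunked causal filtering with carried state equals batch", {
  casc <- build_acquisition_cascade(250)
  set.seed(42)
  x <- rnorm(20000)
  batch <- apply_causal(casc, x)
  cuts <- sort(sample(2:19999, 5))
  pieces <- split(x, findInterval(seq_along(x), cuts))
  st <- NULL; out <- numeric(0)
  for (p in pieces) {
    r <- apply_causal(casc, p, state = st, return_state = TRUE)
    out <- c(out, r$y); st <- r$state
  }
  expect_lt(max(abs(out - batch)), 1e-9)
})

test_that("NaN gaps propagate and reset the filter state", {
  casc <- build_acquisition_cascade(250)
  x <- sin(2 * pi * 3 * (0:2999) / 250)
  x[1000:1200] <- NA
  y <- apply_causal(casc, x)
  expect_true(all(is.na(y[1000:1200])))
  expect_true(all(is.finite(y[1201:3000])))
  # after the gap the output restarts from a reset state: identical to
  # filtering the post-gap segment from scratch
  y2 <- apply_causal(casc, x[1201:3000])
  expect_equal(y[1201:3000], y2, tolerance = 1e-12)
})

test_that("zero-phase filtering has no lag and is reversal-symmetric", {
  fs <- 250
  x <- sin(2 * pi * 1 * (0:4999) / fs)
  z <- apply_zero_phase(x, fs)
  # in-band sinusoid: cross-correlation peaks at lag 0
  expect_gte(cor(z, x), 0.999)
  lags <- -5:5
  cors <- vapply(lags, function(l) {
    idx <- 500:4500
    cor(z[idx], x[idx + l])
  }, numeric(1))
  expect_equal(lags[which.max(cors)], 0)
  # forward/backward symmetry: reversed input gives reversed output
  expect_equal(apply_zero_phase(rev(x), fs), rev(z), tolerance = 1e-8)
  # out-of-band rejection
  x12 <- sin(2 * pi * 12 * (0:4999) / fs)
  expect_lt(sd(apply_zero_phase(x12, fs)) / sd(x12), 0.2)
  expect_error(apply_zero_phase(x[1:5], fs), "short")
})

test_that("analytic-signal phase follows the 90-deg-peak convention", {
  fs <- 250
  t <- (0:4999) / fs
  ph <- instantaneous_phase(sin(2 * pi * 1 * t))
  # peak of sin at t = 0.25 s -> phase 90; ascending zero at t = 1 -> 0/360
  expect_lt(abs(circ_diff_deg(ph[which.min(abs(t - 2.25))], 90)), 2)
  expect_lt(abs(circ_diff_deg(ph[which.min(abs(t - 2.5))], 180)), 2)
  expect_lt(abs(circ_diff_deg(ph[which.min(abs(t - 2.75))], 270)), 2)
})
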