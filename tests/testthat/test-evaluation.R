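test_that("confusion metrics handle perfect, degenerate and zero cases", {
  perf <- confusion_metrics(list(tp = 10, fp = 0, tn = 20, fn = 0))
  expect_equal(perf$sensitivity, 1); expect_equal(perf$specificity, 1)
  expect_equal(perf$precision, 1); expect_equal(perf$accuracy, 1)
  allneg <- confusion_metrics(list(tp = 0, fp = 0, tn = 20, fn = 5))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)
  expect_true(is.na(allneg$precision))          # undefined, flagged not crashed
  tl <- tidy(perf)
  expect_equal(nrow(tl), 4)
})

test_that("epoch confusion tallies match a hand count", {
  ref <- hypnogram(c("N3", "N3", "N2", "W", "N3", "REM"))
  expect_equal(epoch_confusion(ref$stage, ref)$fp, 0)
  expect_equal(epoch_confusion(ref$stage, ref)$fn, 0)
  # shift the labels by one epoch; hand tally: positions of N3 in pred are
  # 2,3,6(wrapped off) vs ref 1,2,5
  pred <- c("W", "N3", "N3", "N2", "W", "N3")
  cm <- epoch_confusion(pred, ref)
  expect_equal(cm$tp, 1)   # epoch 2
  expect_equal(cm$fp, 2)   # epochs 3, 6
  expect_equal(cm$fn, 2)   # epochs 1, 5
  expect_equal(cm$tn, 1)   # epoch 4
  expect_error(epoch_confusion(pred[1:5], ref), "differ")
})

test_that("stage tally assigns events to epochs and computes percentages", {
  ref <- hypnogram(c("W", "N3", "N3", "N2"))
  ev <- tibble::tibble(time_s = c(35, 65, 100), arm = "stim")
  tal <- stage_tally(ev, ref)
  expect_equal(tal$N3, 2); expect_equal(tal$N2, 1)
  pct <- stage_percentages(tal)
  expect_equal(unname(pct$percent["N3"]), 200 / 3, tolerance = 1e-9)
  # toy 3 W + 1 N3
  ev2 <- tibble::tibble(time_s = c(1, 5, 10, 40))
  pct2 <- stage_percentages(stage_tally(ev2, ref))
  expect_equal(unname(pct2$percent["W"]), 75)
  expect_equal(unname(pct2$percent["N3"]), 25)
  # all inside N3
  ev3 <- tibble::tibble(time_s = c(31, 40, 85))
  expect_equal(unname(stage_percentages(stage_tally(ev3, ref))$percent["N3"]), 100)
})

test_that("circular statistics behave on symmetric and uniform samples", {
  expect_equal(circ_mean_deg(c(44, 45, 46)), 45, tolerance = 1e-9)
  expect_equal(circ_mean_deg(c(350, 10)), 0, tolerance = 1e-9)
  expect_equal(circ_sd_deg(rep(45, 10)), 0, tolerance = 1e-6)
  # closed form against direct computation on a known sample
  x <- c(10, 30, 50)
  R <- Mod(mean(exp(1i * x * pi / 180)))
  expect_equal(circ_sd_deg(x), sqrt(-2 * log(R)) * 180 / pi, tolerance = 1e-12)
  set.seed(8)
  u <- runif(1000, 0, 360)
  expect_lte(circ_resultant(u), 0.1)
})

test_that("phase accuracy recovers deliberate 45-degree targeting", {
  fs <- 250
  t <- (0:(250 * fs - 1)) / fs
  f0 <- 1
  x <- 80 * sin(2 * pi * f0 * t)
  # events exactly at the 45-degree ascending phase of each cycle
  ev_t <- (45 / 360) / f0 + seq(5, 240, by = 1 / f0)
  pa <- phase_accuracy(x, fs, ev_t)
  expect_lt(abs(circ_diff_deg(pa$mean_deg, 45)), 3)
  expect_gte(pa$resultant_length, 0.99)
  expect_equal(sum(pa$histogram$count), pa$n)
  expect_equal(nrow(pa$histogram), 72)
  # uniform random events have near-zero resultant
  set.seed(21)
  pa_u <- phase_accuracy(x, fs, runif(1000, 5, 240))
  expect_lte(pa_u$resultant_length, 0.1)
  expect_error(phase_accuracy(x, fs, numeric(0)), "events")
})

test_that("windowed Pearson correlation matches sign and excludes bad windows", {
  set.seed(2)
  x <- rnorm(4000)
  expect_true(all(abs(windowed_pearson(x, x, 250)$r - 1) < 1e-12))
  expect_true(all(abs(windowed_pearson(x, -x, 250)$r + 1) < 1e-12))
  y <- rnorm(4000)
  wp <- windowed_pearson(rnorm(5e5), rnorm(5e5), 250)
  expect_lt(abs(median(wp$r, na.rm = TRUE)), 0.1)
  xb <- x; xb[600] <- NA
  wb <- windowed_pearson(xb, y, 250)
  expect_true(wb$excluded[2])
  expect_true(is.na(wb$r[2]))
})
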