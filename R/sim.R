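# Synthetic sleep-EEG nights with ground truth: stage-dependent spectra,
# discrete slow-oscillation events with known instantaneous phase,
# electrode-detachment artifacts, movements, and two-device clock drift.

#' Simulator configuration
#'
#' Defaults define the study conditions used throughout the package: an 8-h
#' night sampled at 250 Hz (EEG) / 50 Hz (accelerometer), slow oscillations
#' drawn from 0.8--1.2 Hz with 80 microvolt peak amplitude on a 1/f
#' background.
#'
#' @param duration_s Night length in seconds (> 0).
#' @param fs_eeg EEG sampling rate, Hz (default 250; must exceed 36 Hz).
#' @param fs_accel Accelerometer sampling rate, Hz (default 50).
#' @param so_freq_range Slow-oscillation frequency range, Hz.
#' @param so_amplitude_uv Slow-oscillation peak amplitude, microvolts.
#' @param spindle_rate_per_min Spindle rate within N2, events/min.
#' @param artifact_prob_per_epoch Per-epoch probability of a detachment
#'   artifact on one channel.
#' @param movement_rate_per_hour Rate of large body movements, events/hour.
#' @param noise_uv RMS of the 1/f background, microvolts (0 gives a noiseless
#'   record with only the deterministic components).
#' @param seed Integer seed controlling every random draw.
#' @return A `sleep_sim_config` list.
#' @export
sleep_sim_config <- function(duration_s = 8 * 3600, fs_eeg = 250, fs_accel = 50,
                             so_freq_range = c(0.8, 1.2), so_amplitude_uv = 80,
                             spindle_rate_per_min = 3,
                             artifact_prob_per_epoch = 0.03,
                             movement_rate_per_hour = 5,
                             noise_uv = 18, seed = 1L) {
  stopifnot(duration_s > 0, fs_eeg > 36, fs_accel > 0,
            length(so_freq_range) == 2, all(so_freq_range > 0),
            all(so_freq_range < fs_eeg / 2),
            artifact_prob_per_epoch >= 0, artifact_prob_per_epoch <= 1,
            so_amplitude_uv >= 0, noise_uv >= 0)
  structure(list(duration_s = duration_s, fs_eeg = fs_eeg, fs_accel = fs_accel,
                 so_freq_range = so_freq_range, so_amplitude_uv = so_amplitude_uv,
                 spindle_rate_per_min = spindle_rate_per_min,
                 artifact_prob_per_epoch = artifact_prob_per_epoch,
                 movement_rate_per_hour = movement_rate_per_hour,
                 noise_uv = noise_uv, seed = as.integer(seed)),
            class = "sleep_sim_config")
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stage_levels <- c("W", "N1", "N2", "N3", "REM")

#' Construct a hypnogram from stage labels
#'
#' @param stages Character vector of stage labels (`W`, `N1`, `N2`, `N3`,
#'   `REM`), one per 30-s epoch.
#' @param epoch_len_s Epoch length, seconds.
#' @return A `hypnogram` tibble.
#' @export
hypnogram <- function(stages, epoch_len_s = 30) {
  bad <- setdiff(unique(stages), stage_levels)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  new_hypnogram(stages, epoch_len_s)
}

new_hypnogram <- function(stages, epoch_len_s = 30) {
  h <- tibble::tibble(epoch = seq_along(stages),
                      onset_s = (seq_along(stages) - 1) * epoch_len_s,
                      stage = as.character(stages))
  attr(h, "epoch_len_s") <- epoch_len_s
  class(h) <- c("hypnogram", class(h))
  h
}

#' Simulate a night's hypnogram
#'
#' Inhomogeneous first-order Markov stage sequence over 30-s epochs with a
#' conventional NREM-cycle structure (descending N1/N2/N3, ascending N2, REM;
#' N3 pressure decays across cycles). Minimum-dwell rules keep stage bouts
#' physiologically long; in particular the first N3 bout lasts at least 25
#' minutes, so a default 8-h night always carries a contiguous N3 block of 20
#' minutes or more.
#'
#' @param config A [sleep_sim_config()].
#' @return A `hypnogram` tibble (columns `epoch`, `onset_s`, `stage`).
#' @export
simulate_hypnogram <- function(config) {
  stopifnot(inherits(config, "sleep_sim_config"))
  n_epochs <- ceiling(config$duration_s / 30)
  if (config$duration_s < 30) stop("duration shorter than one 30-s epoch")
  with_seed(config$seed, {
    stages <- character(0)
    # dwell = minimum epochs; p = per-epoch probability of staying past the
    # minimum (geometric tail); cap = maximum epochs
    dwell <- function(min_ep, p, cap) min(cap, min_ep + stats::rgeom(1, 1 - p))
    push <- function(st, k) stages <<- c(stages, rep(st, k))
    push("W", dwell(6, 0.90, 30))          # sleep latency
    cycle <- 1
    while (length(stages) < n_epochs) {
      push("N1", dwell(3, 0.70, 12))
      push("N2", dwell(16, 0.95, 45))
      if (cycle <= 3 || runif(1) < 0.6) {
        n3_min <- c(50, 36, 12)[min(cycle, 3)]
        if (cycle >= 4) n3_min <- 6
        n3_cap <- c(90, 70, 40, 25)[min(cycle, 4)]
        push("N3", dwell(n3_min, 0.92, n3_cap))
      }
      push("N2", dwell(10, 0.93, 30))
      push("REM", dwell(6 + 4 * (cycle - 1), 0.93, 50))
      if (runif(1) < 0.3) push("W", dwell(1, 0.5, 4))
      cycle <- cycle + 1
    }
    new_hypnogram(stages[seq_len(n_epochs)])
  })
}

pink_noise <- function(n) {
  if (n < 4) return(rnorm(n))
  nf <- floor((n - 1) / 2)
  f <- seq_len(nf) / n
  amp <- 1 / sqrt(pmax(f, 0.0005))   # flatten the spectrum below ~0.125 Hz at 250 Hz
  ph <- runif(nf) * 2 * pi
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = rep(0, n))
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 1)] <- Conj(spec)
  if (n %% 2 == 0) full[n / 2 + 1] <- rnorm(1) * amp[nf]
  x <- Re(fft(full, inverse = TRUE))
  x / sd(x)
}

band_noise <- function(n, fs, band) {
  if (n < 30) return(rnorm(n))
  bt <- signal::butter(2, pmin(band * 2 / fs, 0.99), type = "pass")
  x <- iir_df2t(bt$b, bt$a, rnorm(n + 500), NULL)$y[-(1:500)]
  s <- sd(x)
  if (s == 0) x else x / s
}

hann_win <- function(n) if (n == 1) 1 else 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Synthesize a labeled night of two-channel EEG plus accelerometer
#'
#' Builds the recording epoch by epoch from the hypnogram: N3 carries discrete
#' one-cycle slow-oscillation events (per-event frequency from
#' `so_freq_range`, ground-truth phase recorded with the 90-degrees-equals-peak
#' convention), N2 carries spindles and occasional K-complexes, wake carries
#' 8--12 Hz activity, N1/REM mixed low-amplitude activity -- all on a shared
#' 1/f background. Detachment artifacts (large drift, one channel at a time)
#' and body movements (accelerometer bursts with a co-timed EEG transient) are
#' injected and logged in the ground truth.
#'
#' @param hypnogram A `hypnogram`.
#' @param config A [sleep_sim_config()].
#' @return `list(recording = , truth = )`: an `mc_recording` and a `sim_truth`.
#' @export
synthesize_night <- function(hypnogram, config) {
  stopifnot(inherits(hypnogram, "hypnogram"), inherits(config, "sleep_sim_config"))
  fs <- config$fs_eeg; fsa <- config$fs_accel
  dur <- config$duration_s
  n <- round(dur * fs); na <- round(dur * fsa)
  stages <- hypnogram$stage
  n_epochs <- nrow(hypnogram)

  with_seed(config$seed + 1L, {
    # --- background: shared + per-channel 1/f, stage-dependent amplitude ---
    mult_by_stage <- c(W = 1.0, N1 = 1.0, N2 = 1.15, N3 = 1.3, REM = 0.85)
    ep_mult <- mult_by_stage[stages]
    samp_mult <- rep(ep_mult, each = 30 * fs)[seq_len(n)]
    # 1-s smoothing so stage transitions are not step discontinuities
    k <- round(fs)
    samp_mult <- as.numeric(data.table::frollmean(samp_mult, k, align = "center",
                                                  fill = NA))
    samp_mult <- data.table::nafill(data.table::nafill(samp_mult, type = "locf"),
                                    type = "nocb")
    shared <- pink_noise(n)
    eeg <- matrix(0, n, 2)
    for (ch in 1:2)
      eeg[, ch] <- config$noise_uv * samp_mult * (0.7 * shared + 0.72 * pink_noise(n))

    t_all <- (seq_len(n) - 1) / fs
    ep_of_sample <- pmin(floor(t_all / 30) + 1, n_epochs)

    add_burst <- function(t0, dur_s, wave_fun, amp, channels = 1:2, taper = TRUE) {
      i0 <- max(1L, floor(t0 * fs) + 1L)
      i1 <- min(n, floor((t0 + dur_s) * fs))
      if (i1 <= i0) return(invisible())
      tt <- (seq(i0, i1) - 1) / fs - t0
      w <- wave_fun(tt) * amp
      if (taper) w <- w * hann_win(length(w))
      for (ch in channels) eeg[seq(i0, i1), ch] <<- eeg[seq(i0, i1), ch] + w
      invisible()
    }

    # --- rhythmic stage signatures ---
    run <- rle(stages)
    run_end <- cumsum(run$lengths); run_start <- run_end - run$lengths + 1
    for (r in seq_along(run$values)) {
      st <- run$values[r]
      t0 <- (run_start[r] - 1) * 30; t1 <- min(run_end[r] * 30, dur)
      i0 <- floor(t0 * fs) + 1; i1 <- min(n, floor(t1 * fs))
      len <- i1 - i0 + 1
      if (len < 10) next
      if (st == "W") {
        alpha <- band_noise(len, fs, c(8, 12)) * 9
        eeg[i0:i1, ] <- eeg[i0:i1, ] + alpha * hann_win(len)^0.25
      } else if (st %in% c("N1", "REM")) {
        theta <- band_noise(len, fs, c(4, 7)) * 6
        eeg[i0:i1, ] <- eeg[i0:i1, ] + theta * hann_win(len)^0.25
      }
    }

    # --- slow oscillations in N3 (one-cycle sine, phase 0 at onset) ---
    so <- list()
    so_id <- 0
    for (r in which(run$values == "N3")) {
      t0 <- (run_start[r] - 1) * 30; t1 <- min(run_end[r] * 30, dur)
      t <- t0 + stats::rexp(1, 1 / 0.8)
      while (TRUE) {
        f <- runif(1, config$so_freq_range[1], config$so_freq_range[2])
        d <- 1 / f
        if (t + d >= t1) break
        amp <- config$so_amplitude_uv * runif(1, 0.85, 1.15)
        add_burst(t, d, function(tt) sin(2 * pi * f * tt), amp, taper = FALSE)
        so_id <- so_id + 1
        so[[so_id]] <- c(t, f, amp, d)
        t <- t + d + stats::rexp(1, 1 / 1.3)
      }
    }
    so_events <- if (so_id > 0) {
      m <- do.call(rbind, so)
      tibble::tibble(event_id = seq_len(nrow(m)), time_s = m[, 1],
                     freq_hz = m[, 2], amplitude_uv = m[, 3], duration_s = m[, 4])
    } else tibble::tibble(event_id = integer(), time_s = numeric(),
                          freq_hz = numeric(), amplitude_uv = numeric(),
                          duration_s = numeric())

    # --- spindles and K-complexes in N2 ---
    for (e in which(stages == "N2")) {
      t0 <- (e - 1) * 30
      ns <- rpois(1, config$spindle_rate_per_min / 2)
      for (s in seq_len(ns)) {
        f <- runif(1, 12, 15); d <- runif(1, 0.7, 1.4)
        ph <- runif(1, 0, 2 * pi)
        add_burst(t0 + runif(1, 0, 30 - d), d,
                  function(tt) sin(2 * pi * f * tt + ph), 28)
      }
      if (runif(1) < 0.25)
        add_burst(t0 + runif(1, 0, 28.5), 1.4,
                  function(tt) -sin(2 * pi * 0.7 * tt), 60)
    }

    # --- accelerometer baseline ---
    accel <- cbind(0.10 + rnorm(na, sd = 0.01),
                   -0.05 + rnorm(na, sd = 0.01),
                   0.98 + rnorm(na, sd = 0.01))

    # --- movements: accel burst plus co-timed EEG transient ---
    n_mov <- rpois(1, config$movement_rate_per_hour * dur / 3600)
    mov_t <- sort(runif(n_mov, 0, max(0, dur - 4)))
    mov_d <- runif(n_mov, 1.2, 3)
    for (m in seq_len(n_mov)) {
      j0 <- floor(mov_t[m] * fsa) + 1
      j1 <- min(na, floor((mov_t[m] + mov_d[m]) * fsa))
      if (j1 <= j0) next
      len <- j1 - j0 + 1
      env <- hann_win(len)^0.5   # flat-topped: a sustained postural excursion
      # movements scale the magnitude itself (well clear of the 1-g baseline),
      # with per-axis jitter for texture
      gain <- 1 + env * runif(1, 0.8, 1.6)
      accel[j0:j1, ] <- accel[j0:j1, ] * gain +
        matrix(rnorm(3 * len, sd = 0.05), len) * env
      add_burst(mov_t[m], mov_d[m],
                function(tt) band_noise(length(tt), fs, c(2, 6)), 110)
    }
    movement_times <- tibble::tibble(time_s = mov_t, duration_s = mov_d)

    # --- detachment artifacts: large slow drift on one channel at a time ---
    art <- list(); ai <- 0
    for (e in seq_len(n_epochs)) {
      if (runif(1) >= config$artifact_prob_per_epoch) next
      ch <- sample(1:2, 1)
      t0 <- (e - 1) * 30 + runif(1, 0, 12)
      d <- runif(1, 4, 16)
      i0 <- floor(t0 * fs) + 1; i1 <- min(n, floor((t0 + d) * fs))
      if (i1 <= i0) next
      len <- i1 - i0 + 1
      drift <- cumsum(rnorm(len))
      drift <- drift / max(abs(drift)) * runif(1, 350, 480)
      eeg[i0:i1, ch] <- eeg[i0:i1, ch] + drift * hann_win(len)^0.2
      eeg[i0:i1, ch] <- pmax(pmin(eeg[i0:i1, ch], 500), -500)   # rail saturation
      ai <- ai + 1
      art[[ai]] <- c(ch, t0, min(t0 + d, dur))
    }
    artifact_intervals <- if (ai > 0) {
      m <- do.call(rbind, art)
      tibble::tibble(channel = as.integer(m[, 1]), start_s = m[, 2], end_s = m[, 3])
    } else tibble::tibble(channel = integer(), start_s = numeric(), end_s = numeric())

    recording <- structure(list(eeg = eeg, accel = accel, fs_eeg = fs,
                                fs_accel = fsa, start_time = 0),
                           class = "mc_recording")
    truth <- structure(list(so_events = so_events,
                            artifact_intervals = artifact_intervals,
                            movement_times = movement_times,
                            stage_per_epoch = hypnogram),
                       class = "sim_truth")
    list(recording = recording, truth = truth)
  })
}

#' Ground-truth slow-oscillation phase at given times
#'
#' @param truth A `sim_truth` from [synthesize_night()].
#' @param times_s Query times in seconds.
#' @return Phase in degrees `[0, 360)` (90 = up-state peak), `NA` outside any
#'   slow-oscillation event.
#' @export
so_true_phase <- function(truth, times_s) {
  ev <- truth$so_events
  if (nrow(ev) == 0) return(rep(NA_real_, length(times_s)))
  idx <- findInterval(times_s, ev$time_s)
  ph <- rep(NA_real_, length(times_s))
  ok <- idx >= 1
  ok[ok] <- times_s[ok] < ev$time_s[idx[ok]] + ev$duration_s[idx[ok]]
  ph[ok] <- (360 * ev$freq_hz[idx[ok]] * (times_s[ok] - ev$time_s[idx[ok]])) %% 360
  ph
}

#' Emulate a second device's clock
#'
#' Resamples/shifts a recording so that its lag relative to the original grows
#' as `offset_s + (fs_ratio - 1) * t`. `fs_ratio` may be a vector (one value
#' per 10-min chunk), giving the piecewise-linear, non-monotonous drift seen
#' between two independently clocked devices.
#'
#' @param recording An `mc_recording`.
#' @param offset_s Initial offset in seconds (the drifted device started
#'   `offset_s` late).
#' @param fs_ratio Clock-rate ratio(s), each in (0.99, 1.01).
#' @param chunk_s Chunk length for piecewise-linear drift (default 600 s).
#' @return A drifted `mc_recording`; samples that map before the start of the
#'   original are `NA`. The true warp is attached as attribute `"drift"`.
#' @export
apply_clock_drift <- function(recording, offset_s, fs_ratio, chunk_s = 600) {
  stopifnot(inherits(recording, "mc_recording"))
  if (any(fs_ratio <= 0.99 | fs_ratio >= 1.01))
    stop("fs_ratio must lie in (0.99, 1.01)")
  dur <- nrow(recording$eeg) / recording$fs_eeg
  n_chunks <- max(1, ceiling(dur / chunk_s))
  ratios <- rep_len(fs_ratio, n_chunks)
  # warp: time on the original clock at which the drifted device takes its
  # sample at (its own) time t
  knots_t <- c(seq(0, by = chunk_s, length.out = n_chunks), dur)
  knots_w <- offset_s + cumsum(c(0, ratios * diff(knots_t)))
  warp <- function(t) approx(knots_t, knots_w, t, rule = 2)$y
  resample <- function(x, fs) {
    t_out <- (seq_along(x) - 1) / fs
    approx((seq_along(x) - 1) / fs, x, warp(t_out), rule = 1)$y
  }
  out <- recording
  for (ch in seq_len(ncol(recording$eeg)))
    out$eeg[, ch] <- resample(recording$eeg[, ch], recording$fs_eeg)
  for (ax in seq_len(ncol(recording$accel)))
    out$accel[, ax] <- resample(recording$accel[, ax], recording$fs_accel)
  attr(out, "drift") <- list(knots_t = knots_t, knots_w = knots_w,
                             offset_s = offset_s, fs_ratio = ratios)
  out
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf("<mc_recording> %d EEG ch x %d samples @ %g Hz, %d accel ch @ %g Hz (%.1f min)\n",
              ncol(x$eeg), nrow(x$eeg), x$fs_eeg, ncol(x$accel), x$fs_accel,
              nrow(x$eeg) / x$fs_eeg / 60))
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d SO events, %d artifact intervals, %d movements, %d epochs\n",
              nrow(x$so_events), nrow(x$artifact_intervals),
              nrow(x$movement_times), nrow(x$stage_per_epoch)))
  invisible(x)
}
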