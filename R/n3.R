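# Epoch-wise N3-vs-else detection: band-power / entropy / complexity features,
# spindle and slow-oscillation event counts, a probability forest, and the
# hard safety conditions (onset delay, movement lockout, 4-h cutoff).

#' Normalized permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution of the delay-embedded
#' series, normalized by `log(order!)` so that 0 means a single pattern
#' (monotone or constant signal) and 1 means all patterns equally likely.
#' Ties are broken by order of appearance (first index wins), so a constant
#' signal maps to one pattern.
#'
#' @param x Numeric signal.
#' @param order Embedding dimension (default 3).
#' @param delay Embedding delay in samples (default 1).
#' @return Normalized entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(x, order = 3, delay = 1) {
  n <- length(x) - (order - 1) * delay
  if (n <= 1) stop("signal too short for the requested order and delay")
  cols <- lapply(seq_len(order) - 1, function(j) x[seq_len(n) + j * delay])
  # Lehmer code with ties resolved toward the earlier index ("<" strict)
  code <- numeric(n)
  fact <- factorial(order - seq_len(order))
  for (i in seq_len(order - 1)) {
    li <- 0
    for (j in (i + 1):order) li <- li + (cols[[j]] < cols[[i]])
    code <- code + li * fact[i]
  }
  p <- tabulate(code + 1, nbins = factorial(order)) / n
  p <- p[p > 0]
  -sum(p * log(p)) / log(factorial(order))
}

higuchi_fd <- function(x, kmax = 8) {
  n <- length(x)
  lk <- vapply(seq_len(kmax), function(k) {
    lm <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) return(NA_real_)
      sum(abs(diff(x[idx]))) * (n - 1) / (k * (length(idx) - 1)) / k
    }, numeric(1))
    mean(lm, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(lk) & lk > 0
  if (sum(ok) < 2) return(1)
  -stats::coef(stats::lm(log(lk[ok]) ~ log(seq_len(kmax)[ok])))[[2]]
}

band_power_fractions <- function(x, fs, bands = list(c(0.4, 4), c(4, 8), c(8, 12), c(12, 18))) {
  x <- x - mean(x)
  P <- Mod(fft(x * hann_win(length(x))))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  f <- pmin(f, fs - f)
  pw <- vapply(bands, function(b) sum(P[f >= b[1] & f < b[2]]), numeric(1))
  tot <- sum(pw)
  if (tot <= 0) rep(1 / length(bands), length(bands)) else pw / tot
}

spectral_entropy <- function(x, fs) {
  x <- x - mean(x)
  P <- Mod(fft(x * hann_win(length(x))))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  f <- pmin(f, fs - f)
  P <- P[f >= 0.4 & f <= 18]
  P <- P / (sum(P) + 1e-300)
  P <- P[P > 0]
  -sum(P * log(P)) / log(length(P))
}

#' Detect sleep spindles in an epoch
#'
#' Events where the 11--16 Hz envelope (zero-phase band-pass, 0.25-s RMS
#' smoothing) exceeds `k` times its epoch median for 0.5--2 s.
#'
#' @param x Epoch samples (microvolts).
#' @param fs Sampling rate, Hz.
#' @param k Envelope threshold multiplier (default 3).
#' @return Tibble with `onset_s`, `duration_s`, `peak_uv` (relative to epoch
#'   start).
#' @export
detect_spindles <- function(x, fs, k = 3) {
  bp <- apply_zero_phase(x, fs, band = c(11, 16), order = 4)
  env <- sqrt(pmax(as.numeric(
    data.table::frollmean(bp^2, round(0.25 * fs), align = "center", fill = NA)), 0))
  env[is.na(env)] <- 0
  thr <- k * stats::median(env[env > 0])
  detect_runs(env > thr, fs, min_s = 0.5, max_s = 2, env = env)
}

#' Detect slow oscillations in an epoch
#'
#' Negative-to-positive waves of the delta-filtered (0.4--4 Hz) signal:
#' successive upward zero-crossings 0.5--2 s apart (consistent with a
#' 0.5--2 Hz wave) whose trough-to-peak amplitude exceeds `amp_uv`.
#'
#' @param x Epoch samples (microvolts).
#' @param fs Sampling rate, Hz.
#' @param amp_uv Trough-to-peak amplitude criterion (default 75).
#' @return Tibble with `onset_s` (upward zero-crossing), `duration_s`,
#'   `peak_uv`, `trough_uv`.
#' @export
detect_slow_oscillations <- function(x, fs, amp_uv = 75) {
  d <- apply_zero_phase(x, fs, band = c(0.4, 4), order = 2)
  up <- which(d[-length(d)] < 0 & d[-1] >= 0)
  empty <- tibble::tibble(onset_s = numeric(), duration_s = numeric(),
                          peak_uv = numeric(), trough_uv = numeric())
  if (length(up) < 2) return(empty)
  i0 <- up[-length(up)]; i1 <- up[-1]
  dur <- (i1 - i0) / fs
  ok <- dur >= 0.5 & dur <= 2
  if (!any(ok)) return(empty)
  pk <- vapply(which(ok), function(i) max(d[i0[i]:i1[i]]), numeric(1))
  tr <- vapply(which(ok), function(i) min(d[i0[i]:i1[i]]), numeric(1))
  big <- pk - tr >= amp_uv
  tibble::tibble(onset_s = (i0[ok][big] - 1) / fs, duration_s = dur[ok][big],
                 peak_uv = pk[big], trough_uv = tr[big])
}

detect_runs <- function(above, fs, min_s, max_s, env) {
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_s * fs & r$lengths <= max_s * fs
  tibble::tibble(onset_s = (starts[keep] - 1) / fs,
                 duration_s = r$lengths[keep] / fs,
                 peak_uv = vapply(which(keep), function(i) max(env[starts[i]:ends[i]]),
                                  numeric(1)))
}

#' Sleep features of a 30-s epoch
#'
#' The feature vector fed to the N3 classifier: relative spectral power in the
#' 0.4--4, 4--8, 8--12 and 12--18 Hz bands (normalized over the 0.4--18 Hz
#' total), normalized permutation entropy, complexity measures (Higuchi
#' fractal dimension, spectral entropy), spindle and slow-oscillation counts,
#' and accelerometer activity. Epochs with more than 50% NaN samples are
#' flagged unscorable and never classified as N3.
#'
#' @param epoch 30 s of virtual-channel samples (NaN allowed).
#' @param accel 30 s of accelerometer samples (matrix, 3 columns), or NULL.
#' @param fs Sampling rate of `epoch`, Hz.
#' @param fs_accel Sampling rate of `accel`, Hz.
#' @return One-row tibble of features with an `unscorable` flag.
#' @export
extract_sleep_features <- function(epoch, accel = NULL, fs = 250, fs_accel = 50) {
  na_frac <- mean(is.na(epoch))
  if (na_frac > 0.5) {
    out <- tibble::tibble(rel_power_0p4_4 = NA_real_, rel_power_4_8 = NA_real_,
                          rel_power_8_12 = NA_real_, rel_power_12_18 = NA_real_,
                          permutation_entropy = NA_real_, higuchi_fd = NA_real_,
                          spectral_entropy = NA_real_, spindle_count = NA_integer_,
                          so_count = NA_integer_, accel_activity = NA_real_,
                          unscorable = TRUE)
    return(out)
  }
  x <- epoch
  if (na_frac > 0) {
    idx <- seq_along(x)
    x <- approx(idx[!is.na(x)], x[!is.na(x)], idx, rule = 2)$y
  }
  bp <- band_power_fractions(x, fs)
  acc_act <- if (is.null(accel)) 0 else {
    mag <- sqrt(rowSums(accel^2))
    sum(abs(mag - stats::median(mag))) / fs_accel
  }
  tibble::tibble(
    rel_power_0p4_4 = bp[1], rel_power_4_8 = bp[2],
    rel_power_8_12 = bp[3], rel_power_12_18 = bp[4],
    permutation_entropy = permutation_entropy(x, 3, 1),
    higuchi_fd = higuchi_fd(x[seq(1, length(x), by = 2)]),
    spectral_entropy = spectral_entropy(x, fs),
    spindle_count = nrow(detect_spindles(x, fs)),
    so_count = nrow(detect_slow_oscillations(x, fs)),
    accel_activity = acc_act,
    unscorable = FALSE)
}

#' Per-epoch sleep features for a whole night
#'
#' Applies [extract_sleep_features()] to every 30-s epoch of a virtual
#' channel.
#'
#' @param virtual A `virtual_channel` from [gate_and_select()].
#' @param accel Optional accelerometer matrix for the same night.
#' @param fs_accel Accelerometer sampling rate, Hz.
#' @return Tibble, one row per epoch, with `epoch` and `onset_s` first.
#' @export
epoch_features_for_night <- function(virtual, accel = NULL, fs_accel = 50) {
  fs <- virtual$fs
  n_epochs <- floor(length(virtual$samples) / (30 * fs))
  purrr::map_dfr(seq_len(n_epochs), function(e) {
    i0 <- (e - 1) * 30 * fs + 1; i1 <- e * 30 * fs
    acc <- NULL
    if (!is.null(accel)) {
      j0 <- (e - 1) * 30 * fs_accel + 1; j1 <- min(nrow(accel), e * 30 * fs_accel)
      acc <- accel[j0:j1, , drop = FALSE]
    }
    extract_sleep_features(virtual$samples[i0:i1], acc, fs, fs_accel) |>
      dplyr::mutate(epoch = e, onset_s = (e - 1) * 30, .before = 1)
  })
}

#' Train the N3-vs-else classifier on simulated nights
#'
#' Simulates labeled nights, extracts per-epoch sleep features from the gated
#' virtual channel, and fits a probability forest for N3 vs every other
#' stage. The decision threshold is then tuned on held-out epochs for high
#' specificity (few false positives), the design goal that matters when a
#' wrong N3 call triggers sounds: among thresholds keeping held-out
#' sensitivity at least `min_sensitivity`, the shipped one maximizes
#' specificity, preferring the more conservative (higher) threshold on ties.
#'
#' @param quality_model A trained `quality_model` used to gate training nights.
#' @param n_nights Number of training nights.
#' @param duration_s Night length for training, seconds.
#' @param seed Integer seed.
#' @param min_sensitivity Sensitivity floor for threshold tuning.
#' @return An `n3_model` (forest, threshold, feature names, version stamp).
#' @export
train_n3_model <- function(quality_model, n_nights = 3, duration_s = 3 * 3600,
                           seed = 200, min_sensitivity = 0.5) {
  dat <- purrr::map_dfr(seq_len(n_nights), function(k) {
    cfg <- sleep_sim_config(duration_s = duration_s, seed = seed + k)
    hyp <- simulate_hypnogram(cfg)
    sim <- synthesize_night(hyp, cfg)
    vc <- gate_and_select(sim$recording, quality_model)
    fe <- epoch_features_for_night(vc, sim$recording$accel, cfg$fs_accel)
    fe$stage <- hyp$stage[fe$epoch]
    fe$night <- k
    fe
  })
  dat <- dplyr::filter(dat, !.data$unscorable)
  dat$is_n3 <- factor(ifelse(dat$stage == "N3", "N3", "else"),
                      levels = c("else", "N3"))
  feat_cols <- c("rel_power_0p4_4", "rel_power_4_8", "rel_power_8_12",
                 "rel_power_12_18", "permutation_entropy", "higuchi_fd",
                 "spectral_entropy", "spindle_count", "so_count", "accel_activity")
  hold <- dat$night == max(dat$night)
  fit <- ranger::ranger(x = dat[!hold, feat_cols], y = dat$is_n3[!hold],
                        probability = TRUE, num.trees = 300, seed = seed)
  p_hold <- predict(fit, data = dat[hold, feat_cols])$predictions[, "N3"]
  truth <- dat$is_n3[hold] == "N3"
  thr_grid <- seq(0.05, 0.95, by = 0.025)
  spec <- vapply(thr_grid, function(th)
    if (any(!truth)) mean(p_hold[!truth] < th) else 1, numeric(1))
  sens <- vapply(thr_grid, function(th)
    if (any(truth)) mean(p_hold[truth] >= th) else 0, numeric(1))
  cand <- which(sens >= min_sensitivity)
  if (!length(cand)) cand <- seq_along(thr_grid)
  threshold <- thr_grid[cand[order(spec[cand], thr_grid[cand],
                                   decreasing = TRUE)[1]]]
  structure(list(forest = fit, threshold = threshold, features = feat_cols,
                 version = "socloop-n3-1"),
            class = "n3_model")
}

#' Probability that an epoch is N3
#'
#' @param features One-row-or-more tibble from [extract_sleep_features()].
#' @param model An `n3_model`.
#' @return Probability (vector) in `[0, 1]`; unscorable epochs are forced to 0.
#' @export
predict_n3 <- function(features, model) {
  if (!inherits(model, "n3_model")) stop("model is not a trained n3_model")
  df <- as.data.frame(features)
  p <- rep(0, nrow(df))
  ok <- !df$unscorable & complete.cases(df[, model$features])
  if (any(ok))
    p[ok] <- predict(model$forest, data = df[ok, model$features])$predictions[, "N3"]
  p
}

#' Hard safety conditions of the stimulation gate
#'
#' Stimulation is allowed only if the current epoch is N3 *and* at least
#' 15 min have elapsed since the first N3 detection *and* no large movement
#' happened less than 3 min ago *and* no more than 4 h have elapsed since the
#' first N3 detection.
#'
#' @param state List with `first_n3_time_s`, `last_large_movement_s`,
#'   `last_time_s` (monotonicity check); use [new_gate_state()] to create.
#' @param now_s Current time, seconds (must not go backwards).
#' @param is_n3 Is the current epoch classified N3?
#' @return `list(allow = logical, state = updated state)`.
#' @export
hard_conditions <- function(state, now_s, is_n3) {
  if (!is.null(state$last_time_s) && now_s < state$last_time_s)
    stop("time must be non-decreasing")
  state$last_time_s <- now_s
  if (is_n3 && is.null(state$first_n3_time_s)) state$first_n3_time_s <- now_s
  allow <- isTRUE(is_n3) && !is.null(state$first_n3_time_s) &&
    now_s >= state$first_n3_time_s + 900 &&
    now_s <= state$first_n3_time_s + 14400 &&
    (is.null(state$last_large_movement_s) ||
       now_s - state$last_large_movement_s >= 180)
  state$stim_window_open <- allow
  list(allow = allow, state = state)
}

#' @rdname hard_conditions
#' @export
new_gate_state <- function() {
  list(first_n3_time_s = NULL, last_large_movement_s = NULL,
       last_time_s = NULL, stim_window_open = FALSE)
}

#' @rdname hard_conditions
#' @param t_s Time of a large movement, seconds.
#' @export
note_movement <- function(state, t_s) {
  state$last_large_movement_s <- max(t_s, state$last_large_movement_s %||% -Inf)
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Large-movement times from the accelerometer
#'
#' A large movement is an excursion of the acceleration magnitude more than
#' 0.5 g away from the 1 g baseline sustained for at least 0.5 s.
#'
#' @param accel Accelerometer matrix (3 columns, g units).
#' @param fs_accel Sampling rate, Hz.
#' @return Tibble with `time_s`, `duration_s`.
#' @export
detect_movements <- function(accel, fs_accel = 50) {
  mag <- sqrt(rowSums(accel^2))
  dev <- abs(mag - stats::median(mag))
  r <- rle(dev > 0.5)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= 0.5 * fs_accel
  tibble::tibble(time_s = (starts[keep] - 1) / fs_accel,
                 duration_s = r$lengths[keep] / fs_accel)
}
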