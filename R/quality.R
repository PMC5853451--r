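# Per-channel signal-quality gating and hysteresis channel switching.
# A quality index q in [0,1] is produced every 0.5 s from the sliding 2-s
# window of each filtered channel; samples of a channel whose index falls
# below the threshold are replaced by NaN, and a hysteresis switch picks the
# better channel as the "virtual channel".

quality_feature_names <- c("na_frac", "rms", "std", "range", "kurtosis",
                           "clip_frac", "flat_frac", "line_ratio", "drift_ratio")

# Vectorized core: M is a samples x windows matrix (NA allowed).
quality_features_matrix <- function(M, fs) {
  nw <- ncol(M); ns <- nrow(M)
  na_frac <- colMeans(is.na(M))
  M0 <- M; M0[is.na(M0)] <- 0
  mu <- .colMeans(M0, ns, nw)
  m2 <- .colMeans(M0^2, ns, nw)
  v <- pmax(m2 - mu^2, 0)
  stdev <- sqrt(v)
  ctr <- sweep(M0, 2, mu)
  m4 <- .colMeans(ctr^4, ns, nw)
  kurt <- ifelse(v > 1e-12, m4 / v^2 - 3, 0)
  tm <- t(M0)
  imax <- max.col(tm, ties.method = "first")
  imin <- max.col(-tm, ties.method = "first")
  mx <- tm[cbind(seq_len(nw), imax)]
  mn <- tm[cbind(seq_len(nw), imin)]
  rng <- mx - mn
  tol <- pmax(0.01 * rng, 1e-9)
  clip <- (.colMeans(sweep(M0, 2, mx - tol) > 0, ns, nw) +
           .colMeans(sweep(M0, 2, mn + tol) < 0, ns, nw))
  clip <- ifelse(rng > 100, clip, 0)   # only meaningful at artifact scale
  dM <- M0[-1, , drop = FALSE] - M0[-ns, , drop = FALSE]
  flat <- .colMeans(abs(dM) < 0.01, ns - 1, nw)
  # spectral ratios from the within-window DFT
  P <- Mod(stats::mvfft(ctr))^2
  f <- (seq_len(ns) - 1) * fs / ns
  f <- pmin(f, fs - f)
  tot <- .colSums(P, ns, nw) + 1e-12
  line <- .colSums(P[f >= 45 & f <= 55, , drop = FALSE], sum(f >= 45 & f <= 55), nw)
  drift <- .colSums(P[f < 1, , drop = FALSE], sum(f < 1), nw)
  out <- cbind(na_frac = na_frac, rms = sqrt(m2), std = stdev, range = rng,
               kurtosis = kurt, clip_frac = clip, flat_frac = flat,
               line_ratio = line / tot, drift_ratio = drift / tot)
  degenerate <- na_frac >= 1 - 1e-12
  out[degenerate, ] <- 0
  out[degenerate, "na_frac"] <- 1
  out
}

#' Quality features of a 2-s window
#'
#' Fixed-length descriptor of how artifacted a window is: amplitude statistics
#' (range, standard deviation, kurtosis), fraction of samples at the amplitude
#' rails (clipping), flatline fraction, power-line band ratio and
#' low-frequency drift power ratio, plus the fraction of NaN samples. An
#' all-NaN window yields the degenerate all-zero vector with `na_frac = 1`.
#'
#' @param window Numeric vector, one 2-s window (NA allowed).
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector of features.
#' @export
quality_features <- function(window, fs) {
  m <- quality_features_matrix(matrix(as.numeric(window), ncol = 1), fs)
  stats::setNames(as.numeric(m[1, ]), colnames(m))
}

#' Quality features for every sliding window of a channel
#'
#' One feature row per 0.5-s step over the trailing 2-s window (the first,
#' not yet full, windows are NA-padded). Vectorized equivalent of calling
#' [quality_features()] per window.
#'
#' @param x Filtered channel samples.
#' @param fs Sampling rate, Hz.
#' @param step_s Decision period, seconds.
#' @param window_s Window length, seconds.
#' @return Tibble with `time_s` (window end) and one column per feature.
#' @export
quality_features_stream <- function(x, fs, step_s = 0.5, window_s = 2) {
  step <- round(step_s * fs); wlen <- round(window_s * fs)
  n <- length(x)
  ends <- seq(step, n, by = step)
  xp <- c(rep(NA_real_, wlen - 1), x)   # so window i is xp[ends[i] .. ends[i]+wlen-1]
  blocks <- split(ends, ceiling(seq_along(ends) / 8192))
  res <- lapply(blocks, function(be) {
    idx <- outer(seq_len(wlen) - 1L, be, `+`)   # wlen x k matrix of indices into xp
    quality_features_matrix(matrix(xp[idx], nrow = wlen), fs)
  })
  feats <- do.call(rbind, res)
  tibble::as_tibble(feats) |> dplyr::mutate(time_s = ends / fs, .before = 1)
}

#' Train the signal-quality classifier on simulator-labeled windows
#'
#' Generates labeled nights with the bundled simulator, extracts 2-s windows of
#' the causally filtered channels, labels each clean or artifacted from the
#' simulator's ground-truth artifact/movement intervals, and fits a
#' probability forest. This plays the role of the embedded quality predictor;
#' the original device's forest and expert-labeled corpus are proprietary, so
#' the classifier here is a synthetic-data analogue.
#'
#' @param n_nights Number of training nights.
#' @param duration_s Length of each training night, seconds.
#' @param seed Integer seed.
#' @param artifact_prob Per-epoch artifact probability used for training data.
#' @return A `quality_model` (ranger forest + feature names + version stamp).
#' @export
train_quality_model <- function(n_nights = 2, duration_s = 7200, seed = 100,
                                artifact_prob = 0.25) {
  dat <- purrr::map_dfr(seq_len(n_nights), function(k) {
    cfg <- sleep_sim_config(duration_s = duration_s, seed = seed + k,
                            artifact_prob_per_epoch = artifact_prob,
                            movement_rate_per_hour = 20)
    hyp <- simulate_hypnogram(cfg)
    sim <- synthesize_night(hyp, cfg)
    casc <- build_acquisition_cascade(cfg$fs_eeg)
    purrr::map_dfr(1:2, function(ch) {
      xf <- apply_causal(casc, sim$recording$eeg[, ch])
      fe <- quality_features_stream(xf, cfg$fs_eeg)
      bad_iv <- dplyr::filter(sim$truth$artifact_intervals, .data$channel == ch)
      bad <- rep(FALSE, nrow(fe))
      for (i in seq_len(nrow(bad_iv)))
        bad <- bad | (fe$time_s > bad_iv$start_s[i] & fe$time_s - 2 < bad_iv$end_s[i])
      mv <- sim$truth$movement_times
      for (i in seq_len(nrow(mv)))
        bad <- bad | (fe$time_s > mv$time_s[i] & fe$time_s - 2 < mv$time_s[i] + mv$duration_s[i])
      dplyr::mutate(fe, clean = factor(ifelse(bad, "bad", "clean"),
                                       levels = c("bad", "clean")))
    })
  })
  dat <- dplyr::filter(dat, .data$na_frac < 1)
  fit <- ranger::ranger(clean ~ ., data = dplyr::select(dat, -"time_s"),
                        probability = TRUE, num.trees = 150, seed = seed)
  structure(list(forest = fit, features = quality_feature_names,
                 version = "socloop-quality-1"),
            class = "quality_model")
}

#' Predict signal quality for feature rows
#'
#' @param features A named feature vector from [quality_features()] or a
#'   tibble of feature rows.
#' @param model A `quality_model`.
#' @return Quality index (indices) in `[0, 1]`; a degenerate all-NaN window
#'   scores 0 by convention.
#' @export
predict_quality <- function(features, model) {
  if (!inherits(model, "quality_model")) stop("model is not a trained quality_model")
  if (is.numeric(features)) features <- tibble::as_tibble(as.list(features))
  df <- as.data.frame(features)[, model$features, drop = FALSE]
  q <- predict(model$forest, data = df)$predictions[, "clean"]
  q[df$na_frac >= 1 - 1e-12] <- 0
  unname(q)
}

#' One step of the hysteresis channel switch
#'
#' Update rule: `s = 1` if `q1 - q2 > theta`, `s = 0` if `q1 - q2 < -theta`,
#' previous state held while `|q1 - q2| <= theta` (equality counts as the
#' dead band, since the printed strict inequalities leave it undefined).
#' Channel 1 feeds the virtual channel while `s = 1`, channel 2 while `s = 0`.
#'
#' @param q1,q2 Channel quality indices in `[0, 1]`.
#' @param state List with elements `s` (0/1) and `theta`.
#' @return Updated state.
#' @export
hysteresis_switch <- function(q1, q2, state = list(s = 1L, theta = 0.2)) {
  d <- q1 - q2
  s <- if (d > state$theta) 1L else if (d < -state$theta) 0L else state$s
  list(s = s, theta = state$theta)
}

#' @rdname hysteresis_switch
#' @param s0 Initial switch state.
#' @param theta Dead-band half-width.
#' @export
hysteresis_path <- function(q1, q2, s0 = 1L, theta = 0.2) {
  s <- integer(length(q1)); prev <- as.integer(s0)
  for (i in seq_along(q1)) {
    d <- q1[i] - q2[i]
    if (is.na(d)) d <- 0
    prev <- if (d > theta) 1L else if (d < -theta) 0L else prev
    s[i] <- prev
  }
  s
}

#' Quality-gate both channels and build the virtual channel
#'
#' Computes the quality index of each causally filtered channel every 0.5 s on
#' the trailing 2-s window, runs the hysteresis switch on the index pair, and
#' expands the per-decision choice to sample resolution: each 0.5-s block of
#' the virtual channel is the selected channel's samples if that channel's
#' quality exceeds `threshold`, NaN otherwise (in particular NaN whenever both
#' channels are bad -- the device never stimulates on bad signal).
#'
#' @param recording An `mc_recording` (raw, unfiltered).
#' @param model A `quality_model`.
#' @param threshold Quality threshold in `[0, 1]` (default 0.5).
#' @param theta Hysteresis dead band (default 0.2).
#' @param cascade Optional pre-built filter cascade (rebuilt from the
#'   recording's rate if omitted).
#' @return A `virtual_channel`: list with `samples` (NaN where gated), `fs`,
#'   `source_flags` (1/2 per sample, 0 in gaps), `quality` tibble
#'   (`time_s`, `q1`, `q2`, `s`) and the filtered channels.
#' @export
gate_and_select <- function(recording, model, threshold = 0.5, theta = 0.2,
                            cascade = NULL) {
  stopifnot(inherits(recording, "mc_recording"))
  fs <- recording$fs_eeg
  if (is.null(cascade)) cascade <- build_acquisition_cascade(fs)
  xf <- apply(recording$eeg, 2, function(ch) apply_causal(cascade, ch))
  f1 <- quality_features_stream(xf[, 1], fs)
  f2 <- quality_features_stream(xf[, 2], fs)
  q1 <- predict_quality(dplyr::select(f1, -"time_s"), model)
  q2 <- predict_quality(dplyr::select(f2, -"time_s"), model)
  s <- hysteresis_path(q1, q2, s0 = 1L, theta = theta)
  quality <- tibble::tibble(time_s = f1$time_s, q1 = q1, q2 = q2, s = s)
  step <- round(0.5 * fs); n <- nrow(xf)
  dec_of_sample <- pmin(ceiling(seq_len(n) / step), length(s))
  sel <- s[dec_of_sample]                       # 1 -> ch1, 0 -> ch2
  q_sel <- ifelse(sel == 1L, q1[dec_of_sample], q2[dec_of_sample])
  src <- ifelse(sel == 1L, 1L, 2L)
  ok <- q_sel > threshold
  samples <- ifelse(ok, ifelse(sel == 1L, xf[, 1], xf[, 2]), NA_real_)
  src[!ok] <- 0L
  structure(list(samples = samples, fs = fs, source_flags = src,
                 quality = quality, filtered = xf),
            class = "virtual_channel")
}
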