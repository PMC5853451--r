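# Alignment of two independently clocked recordings of the same night.
# Each device's crystal runs at a slightly different (and drifting) rate, so
# the lag between the signals is non-linear over the night and can reach
# seconds after 8 h; alignment is solved chunk by chunk as an optimization
# over (translation, sampling-rate ratio) of the band-limited signals.

xcorr_peak <- function(a, b, max_lag) {
  # normalized cross-correlation via FFT; returns lag of b relative to a
  # (positive lag: b delayed) with parabolic sub-sample refinement
  n <- length(a)
  a0 <- a - mean(a); b0 <- b - mean(b)
  L <- stats::nextn(2 * n, 2)
  A <- fft(c(a0, rep(0, L - n)))
  B <- fft(c(b0, rep(0, L - n)))
  cc <- Re(fft(A * Conj(B), inverse = TRUE)) / L
  lags <- c(0:(L / 2 - 1), -(L / 2):-1)
  ok <- abs(lags) <= max_lag
  cci <- cc[ok]; lagi <- lags[ok]
  i <- which.max(cci)
  denom <- sqrt(sum(a0^2) * sum(b0^2))
  score <- if (denom > 0) cci[i] / denom else 0
  lag <- lagi[i]
  # parabolic interpolation around the integer peak
  im <- which(lags == lag - 1); ip <- which(lags == lag + 1)
  if (length(im) && length(ip)) {
    y1 <- cc[im]; y2 <- cci[i]; y3 <- cc[ip]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && abs(den) > 0) lag <- lag + 0.5 * (y1 - y3) / den
  }
  list(lag = lag, score = score)
}

#' Resynchronize a drifting recording to a reference
#'
#' Sequentially, for every 10-min chunk of the reference, finds the
#' translation and sampling-frequency ratio maximizing the normalized
#' cross-correlation with the other device's signal (band-limited to
#' 0.4--18 Hz). Each chunk warm-starts from the previous chunk's solution;
#' chunks scoring below `score_floor` are flagged unalignable.
#'
#' The model per chunk is: the other device's sample at its own time `t`
#' was taken at reference time `offset_s + fs_ratio * (t - chunk_start)`,
#' with `offset_s` reported at the chunk start.
#'
#' @param reference Reference signal (microvolts).
#' @param other Other device's signal.
#' @param fs Common nominal sampling rate, Hz.
#' @param chunk_s Chunk length, seconds (default 600).
#' @param max_offset_s Largest initial offset searched (default 30 s).
#' @param ratio_span Half-width of the ratio grid around the warm start.
#' @param score_floor Minimum correlation for a chunk to count as aligned.
#' @param prefilter Band-limit both signals before aligning (default TRUE).
#' @return Tibble with one row per chunk: `chunk_start_s`, `offset_s`,
#'   `fs_ratio`, `score`, `aligned`.
#' @export
resynchronize <- function(reference, other, fs, chunk_s = 600,
                          max_offset_s = 30, ratio_span = 5e-4,
                          score_floor = 0.2, prefilter = TRUE) {
  if (length(reference) < chunk_s * fs) stop("need at least one full chunk")
  if (prefilter) {
    reference <- apply_zero_phase(ifelse(is.na(reference), 0, reference), fs,
                                  band = c(0.4, 18), order = 4)
    other <- apply_zero_phase(ifelse(is.na(other), 0, other), fs,
                              band = c(0.4, 18), order = 4)
  }
  n_chunks <- floor(length(reference) / (chunk_s * fs))
  r0 <- 1; off0 <- 0
  out <- vector("list", n_chunks)
  for (k in seq_len(n_chunks)) {
    t0 <- (k - 1) * chunk_s
    i0 <- round(t0 * fs) + 1; i1 <- round((t0 + chunk_s) * fs)
    ref_k <- reference[i0:i1]
    max_lag <- if (k == 1) round(max_offset_s * fs) else round(2 * fs)
    guess <- if (k == 1) t0 else off0
    margin <- max_offset_s + 5
    oj0 <- max(1, round((t0 - margin) * fs)); oj1 <- min(length(other), round((t0 + chunk_s + margin) * fs))
    o_sub <- other[oj0:oj1]; t_sub <- (seq(oj0, oj1) - 1) / fs
    score_of <- function(r, return_fit = FALSE) {
      # resample other onto the reference grid of this chunk assuming warp
      # t_ref = guess + r * (t - t0); sample other at t = t0 + (t_ref - guess)/r
      t_ref <- t0 + (seq_len(i1 - i0 + 1) - 1) / fs
      t_q <- t0 + (t_ref - guess) / r
      o_k <- approx(t_sub, o_sub, t_q, rule = 2)$y
      pk <- xcorr_peak(ref_k, o_k, max_lag)
      # a residual lag of `lag` samples means the true offset is guess + lag/fs
      if (return_fit) list(score = pk$score, offset = guess + pk$lag / fs)
      else pk$score
    }
    ratios <- seq(r0 - ratio_span, r0 + ratio_span, by = 1e-4)
    ratios <- ratios[ratios > 0.99 & ratios < 1.01]
    sc <- vapply(ratios, score_of, numeric(1))
    r_best <- ratios[which.max(sc)]
    opt <- stats::optimize(score_of, lower = max(0.99, r_best - 1e-4),
                           upper = min(1.01, r_best + 1e-4), maximum = TRUE,
                           tol = 1e-6)
    fit <- score_of(opt$maximum, return_fit = TRUE)
    aligned <- fit$score >= score_floor
    out[[k]] <- tibble::tibble(chunk_start_s = t0,
                               offset_s = fit$offset - t0,
                               fs_ratio = opt$maximum,
                               score = fit$score, aligned = aligned)
    if (aligned) {
      r0 <- opt$maximum
      # warm start for the next chunk: extrapolate the warp one chunk ahead
      off0 <- fit$offset + r0 * chunk_s
    } else {
      off0 <- guess + chunk_s
    }
  }
  dplyr::bind_rows(out)
}
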