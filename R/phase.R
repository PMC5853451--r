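# Real-time slow-oscillation phase estimation: a forgetting-factor weighted
# least-squares sinusoid fit over a small bank of candidate frequencies
# (0.8--1.2 Hz), the best-correlated frequency winning. Phase convention
# throughout: 0 deg = ascending zero-crossing, 90 deg = up-state peak,
# 270 deg = trough; the stimulation target (45 deg) is mid-ascending slope.

#' Build the sinusoid fit bank
#'
#' For each candidate frequency `f` the design matrix
#' `D_f = [cos(2 pi f t), sin(2 pi f t)]` is formed on the window's time grid
#' and the weighted least-squares solver `W_f = (D_f' L D_f)^-1 D_f' L` is
#' precomputed, where `L` is the diagonal of forgetting-factor weights
#' `lambda^(n-1), ..., lambda, 1` (most recent sample weighted 1). The
#' coefficient estimate for a window `y` is then `theta_f = W_f y`.
#'
#' With the default `lambda = 0.99` the effective memory is about
#' `1/(1-lambda) = 100` samples; the window length is parameterized
#' separately (default 2 s at the stream's rate) since the two published
#' readings of the memory length disagree.
#'
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, seconds (default 2).
#' @param lambda_ Forgetting factor in (0, 1] (default 0.99).
#' @param freq_list Candidate frequencies, Hz (default `c(0.8, 0.9, 1, 1.1, 1.2)`).
#' @return A `sinusoid_fit_bank`.
#' @export
build_fit_bank <- function(fs, window_s = 2, lambda_ = 0.99,
                           freq_list = c(0.8, 0.9, 1.0, 1.1, 1.2)) {
  n <- round(window_s * fs)
  if (n < 4) stop("window too short")
  t <- (seq_len(n) - 1) / fs
  w <- lambda_^((n - 1):0)
  fits <- lapply(freq_list, function(f) {
    D <- cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))
    M <- crossprod(D, w * D)            # D' L D
    V <- tryCatch(solve(M), error = function(e)
      stop("singular normal matrix for f = ", f))
    W <- V %*% t(w * D)                 # V D' L
    list(freq = f, D = D, M = M, W = W)
  })
  structure(list(fs = fs, n = n, t = t, lambda_ = lambda_, w = w,
                 freq_list = freq_list, fits = fits),
            class = "sinusoid_fit_bank")
}

phase_from_theta <- function(theta, omega_t) {
  a <- theta[1]; b <- theta[2]
  # fitted s(t) = a cos + b sin = A sin(omega t + phi0); instantaneous phase
  # psi with s = A sin(psi), ascending at psi = 0, peak at 90 deg
  (atan2(a * cos(omega_t) + b * sin(omega_t),
         b * cos(omega_t) - a * sin(omega_t)) * 180 / pi) %% 360
}

#' Estimate slow-oscillation phase from the newest window
#'
#' Fits every frequency of the bank to the buffer, scores each fit by the
#' fraction of forgetting-weighted signal energy it explains (in `[0, 1]`),
#' keeps the best frequency, and reads the phase of the fitted sinusoid at
#' the newest sample. Buffers containing NaN, or with no energy, give an
#' invalid estimate.
#'
#' @param bank A `sinusoid_fit_bank`.
#' @param buffer Numeric vector of the newest `bank$n` samples (oldest first).
#' @return A `phase_estimate` list: `freq`, `phi` (fit phase offset, deg),
#'   `phase_now` (deg at the newest sample), `correlation`, `valid`.
#' @export
estimate_phase <- function(bank, buffer) {
  stopifnot(inherits(bank, "sinusoid_fit_bank"), length(buffer) == bank$n)
  invalid <- list(freq = NA_real_, phi = NA_real_, phase_now = NA_real_,
                  correlation = NA_real_, valid = FALSE)
  class(invalid) <- "phase_estimate"
  if (anyNA(buffer)) return(invalid)
  energy <- sum(bank$w * buffer^2)
  if (energy <= 0) return(invalid)
  best <- NULL; best_corr <- -Inf
  for (ft in bank$fits) {
    theta <- as.numeric(ft$W %*% buffer)
    explained <- as.numeric(crossprod(theta, ft$M %*% theta))
    corr <- sqrt(max(0, min(1, explained / energy)))
    if (corr > best_corr) { best_corr <- corr; best <- list(ft = ft, theta = theta) }
  }
  ft <- best$ft; theta <- best$theta
  t_new <- bank$t[bank$n]
  structure(list(
    freq = ft$freq,
    phi = (atan2(theta[1], theta[2]) * 180 / pi) %% 360,
    phase_now = phase_from_theta(theta, 2 * pi * ft$freq * t_new),
    correlation = best_corr,
    valid = TRUE), class = "phase_estimate")
}

#' @export
print.phase_estimate <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<phase_estimate> f = %.1f Hz, phase_now = %.1f deg, corr = %.3f\n",
                x$freq, x$phase_now, x$correlation))
  else cat("<phase_estimate> invalid\n")
  invisible(x)
}

#' Vectorized phase trace over a whole signal
#'
#' Computes, for every sample, exactly the estimate [estimate_phase()] would
#' produce from the trailing window, using FFT-based FIR filtering (the two
#' rows of each `W_f` act as FIR kernels). Samples whose trailing window is
#' incomplete or contains NaN are invalid.
#'
#' @param bank A `sinusoid_fit_bank`.
#' @param x Signal (microvolts; NaN allowed).
#' @return Tibble with `idx`, `time_s`, `freq`, `phase_now`, `correlation`,
#'   `valid`.
#' @export
phase_trace <- function(bank, x) {
  n <- bank$n; N <- length(x)
  bad <- is.na(x)
  x0 <- ifelse(bad, 0, x)
  nbad <- as.numeric(data.table::frollsum(as.numeric(bad), n, align = "right", fill = 1))
  energy <- as.numeric(signal::fftfilt(rev(bank$w), x0^2))
  nf <- length(bank$fits)
  corr <- matrix(-Inf, N, nf); A <- matrix(0, N, nf); B <- matrix(0, N, nf)
  for (j in seq_len(nf)) {
    ft <- bank$fits[[j]]
    a <- as.numeric(signal::fftfilt(rev(ft$W[1, ]), x0))
    b <- as.numeric(signal::fftfilt(rev(ft$W[2, ]), x0))
    explained <- ft$M[1, 1] * a^2 + 2 * ft$M[1, 2] * a * b + ft$M[2, 2] * b^2
    corr[, j] <- sqrt(pmax(0, pmin(1, explained / pmax(energy, 1e-300))))
    A[, j] <- a; B[, j] <- b
  }
  bestj <- max.col(corr, ties.method = "first")
  sel <- cbind(seq_len(N), bestj)
  a <- A[sel]; b <- B[sel]
  freq <- bank$freq_list[bestj]
  t_new <- bank$t[n]
  om <- 2 * pi * freq * t_new
  phase_now <- (atan2(a * cos(om) + b * sin(om),
                      b * cos(om) - a * sin(om)) * 180 / pi) %% 360
  valid <- seq_len(N) >= n & nbad == 0 & energy > 0
  tibble::tibble(idx = seq_len(N), time_s = (seq_len(N) - 1) / bank$fs,
                 freq = ifelse(valid, freq, NA_real_),
                 phase_now = ifelse(valid, phase_now, NA_real_),
                 correlation = ifelse(valid, corr[sel], NA_real_),
                 valid = valid)
}

#' Did the phase cross the stimulation target?
#'
#' TRUE iff the phase advanced across `target_deg` in the ascending direction
#' between two consecutive estimates (modular interval test; advances of half
#' a cycle or more are not treated as crossings). Both estimates must be
#' valid.
#'
#' @param prev,curr Consecutive `phase_estimate`s (or numeric phases in
#'   degrees).
#' @param target_deg Target phase (default 45).
#' @return Logical.
#' @export
detect_target_crossing <- function(prev, curr, target_deg = 45) {
  p <- if (inherits(prev, "phase_estimate")) {
    if (!prev$valid) return(FALSE) else prev$phase_now
  } else prev
  c_ <- if (inherits(curr, "phase_estimate")) {
    if (!curr$valid) return(FALSE) else curr$phase_now
  } else curr
  if (is.na(p) || is.na(c_)) return(FALSE)
  adv <- (c_ - p) %% 360
  to_target <- (target_deg - p) %% 360
  adv < 180 && to_target > 0 && to_target <= adv
}

crossing_vector <- function(phase_now, valid, target_deg = 45) {
  N <- length(phase_now)
  p <- c(NA_real_, phase_now[-N])
  vp <- c(FALSE, valid[-N])
  adv <- (phase_now - p) %% 360
  tt <- (target_deg - p) %% 360
  out <- valid & vp & !is.na(adv) & adv < 180 & tt > 0 & tt <= adv
  out[is.na(out)] <- FALSE
  out
}
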