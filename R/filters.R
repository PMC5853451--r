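#' Acquisition filter cascade
#'
#' Designs the causal front-end cascade applied to each raw EEG channel before
#' any downstream processing: a 4th-order Butterworth band-pass restricting the
#' signal to the 0.4--18 Hz range relevant for sleep analysis, followed by
#' three narrow band-stop stages removing the 60 Hz and 50 Hz power-line
#' components and a 62--63 Hz hardware calibration tone (order-2 Bessel).
#'
#' Stages whose upper stop-band edge reaches the Nyquist frequency cannot be
#' realized and are dropped with a warning; the band-pass stage is always kept.
#'
#' @param fs Sampling rate in Hz (must be at least 36 Hz so that the 0.4--18 Hz
#'   pass band is below Nyquist).
#' @return A `filter_cascade` object: a list with `stages` (tibble describing
#'   each stage), `coef` (list of `b`/`a` coefficient pairs) and `fs`.
#' @examples
#' casc <- build_acquisition_cascade(250)
#' casc$stages
#' @export
build_acquisition_cascade <- function(fs) {
  if (!is.numeric(fs) || length(fs) != 1 || fs < 36)
    stop("fs must be a single number >= 36 Hz (pass band extends to 18 Hz)")
  stages <- tibble::tibble(
    family = c("butterworth", "butterworth", "butterworth", "bessel"),
    kind   = c("bandpass", "bandstop", "bandstop", "bandstop"),
    order  = c(4L, 6L, 6L, 2L),
    f_lo   = c(0.4, 58, 48, 62),
    f_hi   = c(18, 62, 52, 63)
  )
  keep <- stages$kind == "bandpass" | stages$f_hi < fs / 2
  if (any(!keep)) {
    dropped <- stages[!keep, ]
    warning(sprintf("dropping %d stop-band stage(s) at/above Nyquist (%g Hz): %s",
                    nrow(dropped), fs / 2,
                    paste(sprintf("%g-%g Hz", dropped$f_lo, dropped$f_hi), collapse = ", ")))
    stages <- stages[keep, ]
  }
  coef <- purrr::pmap(stages, function(family, kind, order, f_lo, f_hi) {
    design_stage(family, kind, order, c(f_lo, f_hi), fs)
  })
  structure(list(stages = stages, coef = coef, fs = fs), class = "filter_cascade")
}

# Printed orders are overall filter orders; signal::butter() doubles the order
# for pass/stop bands, hence order/2.
design_stage <- function(family, kind, order, band, fs) {
  w <- band * 2 / fs
  if (family == "butterworth") {
    if (order %% 2 != 0) stop("band filters need an even overall order")
    bt <- signal::butter(order / 2, w, type = if (kind == "bandstop") "stop" else "pass")
    list(b = bt$b, a = bt$a)
  } else if (family == "bessel") {
    if (order != 2) stop("only the order-2 Bessel band-stop is supported")
    if (kind != "bandstop") stop("Bessel stage must be a band-stop")
    # analog order-2 Bessel low-pass prototype: poles of s^2 + 3 s + 3
    p <- polyroot(c(3, 3, 1))
    warped <- 2 * fs * tan(pi * band / fs)      # prewarp for the bilinear map
    st <- signal::sftrans(Sz = numeric(0), Sp = p, Sg = 3, W = warped, stop = TRUE)
    dg <- signal::bilinear(Sz = st$zero, Sp = st$pole, Sg = st$gain, T = 1 / fs)
    ba <- signal::as.Arma(dg)
    list(b = Re(ba$b), a = Re(ba$a))
  } else stop("unknown filter family: ", family)
}

#' Apply the causal cascade to a signal
#'
#' Streaming-safe causal filtering: passing the carried `state` from a previous
#' call makes chunked application bit-equivalent (to ~1e-9) to filtering the
#' whole signal at once. `NA`/`NaN` samples propagate to the output and reset
#' the filter state, so transients do not leak across gaps where an electrode
#' was detached.
#'
#' @param cascade A `filter_cascade` from [build_acquisition_cascade()].
#' @param x Numeric signal (microvolts); `NA` marks gaps.
#' @param state Optional state list returned by a previous call.
#' @param return_state If `TRUE`, return `list(y, state)` instead of `y`.
#' @return Filtered signal, or `list(y = , state = )` when `return_state`.
#' @export
apply_causal <- function(cascade, x, state = NULL, return_state = FALSE) {
  stopifnot(inherits(cascade, "filter_cascade"))
  y <- as.numeric(x)
  new_state <- vector("list", length(cascade$coef))
  for (i in seq_along(cascade$coef)) {
    cf <- cascade$coef[[i]]
    r <- iir_df2t(cf$b, cf$a, y, if (is.null(state)) NULL else state[[i]])
    y <- r$y
    new_state[[i]] <- r$zf
  }
  if (return_state) list(y = y, state = new_state) else y
}

#' Zero-phase band-pass filtering
#'
#' Forward/backward (non-causal) Butterworth filtering with odd-reflection
#' padding, used for all offline analyses where phase delays would bias
#' results: instantaneous-phase measurement in the delta band and ERP
#' preprocessing.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param band Length-2 pass band in Hz (default the 0.4--4 Hz delta band).
#' @param order Overall filter order (even; default 2).
#' @return Filtered signal, same length as `x`.
#' @export
apply_zero_phase <- function(x, fs, band = c(0.4, 4), order = 2) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] < fs / 2, order %% 2 == 0)
  bt <- signal::butter(order / 2, band * 2 / fs, type = "pass")
  # pad by ~3 time constants of the low edge so start/end transients die out
  npad <- min(length(x) - 1, round(3 * fs / band[1]))
  if (length(x) <= 3 * max(length(bt$a), length(bt$b)))
    stop("signal too short for zero-phase filtering")
  # odd reflection at both ends suppresses edge transients
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)]
  xp <- c(pre, x, post)
  y <- iir_df2t(bt$b, bt$a, xp, NULL)$y
  y <- rev(iir_df2t(bt$b, bt$a, rev(y), NULL)$y)
  y[(npad + 1):(npad + length(x))]
}

#' Frequency response of a cascade
#'
#' @param cascade A `filter_cascade`.
#' @param f Frequencies (Hz) at which to evaluate the response.
#' @return Complex response vector, one value per frequency.
#' @export
cascade_freq_response <- function(cascade, f) {
  z <- exp(2i * pi * f / cascade$fs)
  h <- rep(1 + 0i, length(f))
  for (cf in cascade$coef) {
    num <- vapply(z, function(zz) sum(cf$b * zz^-(seq_along(cf$b) - 1)), complex(1))
    den <- vapply(z, function(zz) sum(cf$a * zz^-(seq_along(cf$a) - 1)), complex(1))
    h <- h * num / den
  }
  h
}

#' Check stability of every stage of a cascade
#' @param cascade A `filter_cascade`.
#' @return `TRUE` if all poles of all stages lie strictly inside the unit circle.
#' @export
cascade_is_stable <- function(cascade) {
  all(vapply(cascade$coef, function(cf) {
    all(Mod(polyroot(rev(cf$a))) < 1)
  }, logical(1)))
}

#' Analytic-signal instantaneous phase
#'
#' FFT-based analytic signal; phase is mapped to the slow-oscillation
#' convention used throughout the package: 0 deg = ascending zero-crossing,
#' 90 deg = up-state peak, 270 deg = down-state trough.
#'
#' @param x Real signal (typically delta-band filtered).
#' @return Phase in degrees in `[0, 360)`, one value per sample.
#' @export
instantaneous_phase <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / n
  # For x = sin(phase), Arg(analytic) = phase - 90 deg; shift back.
  (Arg(z) * 180 / pi + 90) %% 360
}
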