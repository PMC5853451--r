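# Event-related potentials around stimulation triggers and the delta-power
# increase statistic comparing stimulated and sham trains.

#' Extract trigger-locked epochs
#'
#' Cuts a window around each event; epochs clipped by the recording edges are
#' dropped (their count is reported via a message). The signal should already
#' be filtered with the zero-phase (forward/backward) scheme so trigger-locked
#' averages carry no phase delay.
#'
#' @param x Signal (microvolts).
#' @param fs Sampling rate, Hz.
#' @param event_times_s Trigger times, seconds.
#' @param window Length-2 window around the trigger, seconds (default
#'   `c(-1, 4)`).
#' @return Matrix (events x samples) with attribute `time_s` (time axis
#'   relative to the trigger) and `kept` (logical per input event).
#' @export
extract_event_epochs <- function(x, fs, event_times_s, window = c(-1, 4)) {
  stopifnot(length(window) == 2, window[2] > window[1])
  i_rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1)
  i_ev <- round(event_times_s * fs) + 1
  kept <- i_ev + i_rel[1] >= 1 & i_ev + i_rel[length(i_rel)] <= length(x)
  if (any(!kept))
    message(sum(!kept), " epoch(s) dropped at recording edges")
  m <- t(vapply(i_ev[kept], function(i) x[i + i_rel], numeric(length(i_rel))))
  if (length(i_ev[kept]) == 1) m <- matrix(m, nrow = 1)
  attr(m, "time_s") <- i_rel / fs
  attr(m, "kept") <- kept
  m
}

#' Trigger-locked average ERP per condition
#'
#' @param x Zero-phase-filtered signal.
#' @param fs Sampling rate, Hz.
#' @param events Stim log tibble with `time_s`, `arm`, `pulse_index`.
#' @param lock Lock to the `"first"` or `"second"` pulse of each train.
#' @param window Window around the trigger, seconds.
#' @return An `erp_result` tibble: `time_s`, `arm`, `mean_uv`, `sd_uv`, `n`.
#' @export
erp_average <- function(x, fs, events, lock = c("first", "second"),
                        window = c(-1, 4)) {
  lock <- match.arg(lock)
  pi_target <- if (lock == "first") 1L else 2L
  ev <- dplyr::filter(events, .data$pulse_index == pi_target)
  out <- purrr::map_dfr(split(ev, ev$arm), function(e) {
    if (!nrow(e)) return(NULL)
    m <- extract_event_epochs(x, fs, e$time_s, window)
    tibble::tibble(time_s = attr(m, "time_s"), arm = e$arm[1],
                   mean_uv = colMeans(m), sd_uv = apply(m, 2, sd),
                   n = nrow(m))
  })
  class(out) <- c("erp_result", class(out))
  out
}

#' Delta power of a post-trigger segment
#'
#' The squared norm of the discrete Fourier transform of the first `n_steps`
#' samples after the trigger, tapered with a Hann window, summed over bins
#' whose frequency falls in `band`. At 250 Hz the default 1024 steps span
#' 4.096 s -- the "4-s window" realization.
#'
#' @param epoch Samples starting at the trigger (length >= `n_steps`).
#' @param fs Sampling rate, Hz.
#' @param n_steps DFT length (default 1024).
#' @param band Frequency band, Hz (default 0.4--4).
#' @return Band power in microvolts squared.
#' @export
delta_power_window <- function(epoch, fs, n_steps = 1024, band = c(0.4, 4)) {
  if (length(epoch) < n_steps) stop("epoch shorter than the DFT window")
  seg <- epoch[seq_len(n_steps)] * hann_win(n_steps)
  P <- Mod(fft(seg))^2
  f <- (seq_len(n_steps) - 1) * fs / n_steps
  f <- pmin(f, fs - f)   # fold negative frequencies onto their mirror
  sum(P[f >= band[1] & f <= band[2]])
}

#' Per-event delta powers for a stimulation log
#'
#' For each train, takes the window anchored at the first pulse (or starting
#' `second_offset_s` after the second pulse) and computes its delta power.
#'
#' @param x Signal (microvolts).
#' @param fs Sampling rate, Hz.
#' @param events Stim log with `time_s`, `arm`, `train_index`, `pulse_index`.
#' @param anchor `"first"` or `"second"` pulse of the train.
#' @param second_offset_s Window start relative to the second pulse when
#'   `anchor = "second"` (default 1 s; the window then covers the seconds
#'   following the end of the second oscillation).
#' @param subject Optional subject id recycled onto the result.
#' @param n_steps,band Passed to [delta_power_window()].
#' @return Tibble with `subject`, `train_index`, `arm`, `delta_power`.
#' @export
compute_delta_powers <- function(x, fs, events, anchor = c("first", "second"),
                                 second_offset_s = 1, subject = "s1",
                                 n_steps = 1024, band = c(0.4, 4)) {
  anchor <- match.arg(anchor)
  pi_target <- if (anchor == "first") 1L else 2L
  ev <- dplyr::filter(events, .data$pulse_index == pi_target)
  t0 <- ev$time_s + if (anchor == "second") second_offset_s else 0
  keep <- round(t0 * fs) + n_steps <= length(x) & t0 >= 0
  ev <- ev[keep, ]; t0 <- t0[keep]
  pw <- vapply(t0, function(tt) {
    i0 <- round(tt * fs) + 1
    delta_power_window(x[i0:(i0 + n_steps - 1)], fs, n_steps, band)
  }, numeric(1))
  tibble::tibble(subject = subject, train_index = ev$train_index,
                 arm = ev$arm, delta_power = pw)
}

#' Delta-power increase of stimulation over sham
#'
#' Averages delta power within subject and condition, then compares the two
#' per-subject distributions: the percent increase is
#' `(mean(stim) / mean(sham) - 1) * 100` over the distribution means, and a
#' paired t-test across subjects tests the difference (significance
#' conventionally at p < 0.001).
#'
#' @param powers Tibble with `subject`, `arm` (`"stim"`/`"sham"`) and
#'   `delta_power`, e.g. from [compute_delta_powers()] (rows may pool several
#'   nights per subject).
#' @return A `delta_power_comparison`: list with `per_subject` tibble,
#'   `percent_increase`, `t_statistic`, `p_value`, `n_subjects`.
#' @export
delta_power_comparison <- function(powers) {
  per <- powers |>
    dplyr::group_by(.data$subject, .data$arm) |>
    dplyr::summarise(mean_power = mean(.data$delta_power), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "mean_power")
  if (!all(c("stim", "sham") %in% names(per)))
    stop("both a stim and a sham arm are required")
  per <- dplyr::filter(per, !is.na(.data$stim) & !is.na(.data$sham))
  if (nrow(per) < 2) stop("paired test requires at least two subjects")
  tt <- t.test(per$stim, per$sham, paired = TRUE)
  structure(list(per_subject = per,
                 percent_increase = (mean(per$stim) / mean(per$sham) - 1) * 100,
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 n_subjects = nrow(per)),
            class = "delta_power_comparison")
}

#' @export
print.delta_power_comparison <- function(x, ...) {
  cat(sprintf("<delta_power_comparison> n = %d subjects, increase = %.2f%%, t = %.2f, p = %.3g\n",
              x$n_subjects, x$percent_increase, x$t_statistic, x$p_value))
  invisible(x)
}

#' Pointwise comparison of ERP differences between two nights
#'
#' For habituation analyses: each subject contributes a (stim - sham) ERP
#' difference trace per night; a paired t-test at every timepoint compares
#' night A to night B, flagging p < `alpha`.
#'
#' @param night_a,night_b Matrices (subjects x timepoints) of ERP
#'   differences, with matching `rownames` identifying subjects.
#' @param alpha Significance threshold (default 0.001).
#' @return Tibble with `timepoint`, `t_statistic`, `p_value`, `significant`.
#' @export
compare_nights <- function(night_a, night_b, alpha = 0.001) {
  if (is.null(rownames(night_a)) || is.null(rownames(night_b)) ||
      !setequal(rownames(night_a), rownames(night_b)))
    stop("the two nights must cover the same subjects")
  if (ncol(night_a) != ncol(night_b)) stop("time axes differ")
  night_b <- night_b[rownames(night_a), , drop = FALSE]
  d <- night_a - night_b
  n <- nrow(d)
  mu <- colMeans(d)
  se <- apply(d, 2, sd) / sqrt(n)
  tstat <- ifelse(se > 0, mu / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p[se == 0] <- 1
  tibble::tibble(timepoint = seq_along(mu), t_statistic = tstat,
                 p_value = p, significant = p < alpha)
}
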