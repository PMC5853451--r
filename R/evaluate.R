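# Offline performance metrics: epoch-wise confusion matrix for N3 detection,
# stimulation-by-stage tallies, circular phase accuracy (Hilbert method),
# and windowed Pearson correlation between devices.

#' Confusion-matrix metrics for N3 detection
#'
#' @param counts Named list/vector or one-row data frame with `tp`, `fp`,
#'   `tn`, `fn` (epoch counts, N3 = positive class).
#' @return A `confusion_result` tibble with the counts and `sensitivity`
#'   (tp/(tp+fn)), `specificity` (tn/(tn+fp)), `precision` (tp/(tp+fp)) and
#'   `accuracy`; a zero denominator yields `NA` for the affected metric.
#' @examples
#' confusion_metrics(list(tp = 8610, fp = 3017, tn = 27009, fn = 3666))
#' @export
confusion_metrics <- function(counts) {
  cc <- as.list(counts)
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  out <- tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    total = tp + fp + tn + fn,
    positives = tp + fn,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    precision = safe_div(tp, tp + fp),
    accuracy = safe_div(tp + tn, tp + fp + tn + fn))
  class(out) <- c("confusion_result", class(out))
  out
}

#' Epoch-wise confusion counts of predicted vs reference staging
#'
#' @param predicted Logical vector (is the epoch N3?), or a tibble with an
#'   `is_n3` column, or a character stage vector.
#' @param reference A `hypnogram` or character stage vector of equal length.
#' @return A `confusion_result` (via [confusion_metrics()]).
#' @export
epoch_confusion <- function(predicted, reference) {
  p <- if (is.data.frame(predicted)) predicted$is_n3
       else if (is.character(predicted)) predicted == "N3"
       else as.logical(predicted)
  r <- if (is.data.frame(reference)) reference$stage == "N3"
       else if (is.character(reference)) reference == "N3"
       else as.logical(reference)
  if (length(p) != length(r)) stop("predicted and reference epoch counts differ")
  confusion_metrics(list(tp = sum(p & r), fp = sum(p & !r),
                         tn = sum(!p & !r), fn = sum(!p & r)))
}

#' Tally stimulation events by sleep stage
#'
#' Assigns each event to the 30-s epoch of the reference hypnogram containing
#' it and tallies counts per stage and arm; events outside the hypnogram span
#' are counted as `NS` (not scored).
#'
#' @param events Stim log tibble with `time_s` and optionally `arm`.
#' @param reference A `hypnogram`.
#' @return Counts tibble (`arm`, one column per stage, `total`); pass it to
#'   [stage_percentages()] for the percentage breakdown.
#' @export
stage_tally <- function(events, reference) {
  epoch_len <- attr(reference, "epoch_len_s") %||% 30
  if (!"arm" %in% names(events)) events$arm <- "all"
  ep <- floor(events$time_s / epoch_len) + 1
  stage <- rep("NS", nrow(events))
  inside <- ep >= 1 & ep <= nrow(reference)
  stage[inside] <- reference$stage[ep[inside]]
  lv <- c("W", "N1", "N2", "N3", "REM", "NS")
  tab <- table(factor(events$arm), factor(stage, levels = lv))
  out <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "arm")
  out$total <- rowSums(tab)
  out
}

#' Percentage breakdown of a stage tally
#'
#' Percentages are computed over the grand total of events pooled across
#' arms, matching how stimulation-by-stage results are conventionally
#' reported; row totals per arm are preserved.
#'
#' @param counts Counts tibble as returned by [stage_tally()] (columns `arm`,
#'   stages, optionally `total`).
#' @return List with `percent` (named stage percentages over the grand
#'   total), `row_totals` (named per-arm totals) and `grand_total`.
#' @examples
#' counts <- tibble::tibble(arm = c("SHAM", "STIM"),
#'   W = c(122, 267), N1 = c(68, 70), N2 = c(1760, 2126),
#'   N3 = c(15343, 15112), REM = c(282, 197), NS = c(4, 14))
#' stage_percentages(counts)$percent
#' @export
stage_percentages <- function(counts) {
  stage_cols <- intersect(c("W", "N1", "N2", "N3", "REM", "NS"), names(counts))
  m <- as.matrix(counts[, stage_cols])
  row_totals <- rowSums(m)
  names(row_totals) <- counts$arm
  grand <- sum(m)
  pct <- 100 * colSums(m) / grand
  list(percent = pct, row_totals = row_totals, grand_total = grand)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Circular mean of angles in degrees
#' @param deg Angles in degrees.
#' @return Mean direction in `[0, 360)`.
#' @export
circ_mean_deg <- function(deg) {
  m <- rad2deg(Arg(mean(exp(1i * deg2rad(deg))))) %% 360
  if (m > 360 - 1e-9) 0 else m   # guard against -eps wrapping to 360
}

#' Resultant length of angles in degrees
#' @param deg Angles in degrees.
#' @return `R` in `[0, 1]`.
#' @export
circ_resultant <- function(deg) Mod(mean(exp(1i * deg2rad(deg))))

#' Circular standard deviation, degrees
#'
#' `sqrt(-2 log R)` expressed in degrees, the standard dispersion measure for
#' angular data.
#' @param deg Angles in degrees.
#' @export
circ_sd_deg <- function(deg) {
  R <- circ_resultant(deg)
  rad2deg(sqrt(-2 * log(max(R, 1e-12))))
}

#' Signed circular distance a - b in (-180, 180]
#' @param a,b Angles in degrees.
#' @export
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Circular accuracy of stimulation timing
#'
#' Measures the instantaneous delta-band phase at each pulse: the EEG is
#' filtered with a zero-phase second-order Butterworth band-pass (0.4--4 Hz),
#' the analytic-signal phase is read at each event time (90 deg = up-state
#' peak), and the distribution is summarized by its circular mean, circular
#' SD (`sqrt(-2 log R)`), resultant length and a 72-bin (5-degree) histogram.
#'
#' @param x EEG samples (microvolts).
#' @param fs Sampling rate, Hz.
#' @param event_times_s Pulse times in seconds (at least one, inside the
#'   recording).
#' @return A `circular_summary`: list with `n`, `mean_deg`, `sd_deg`,
#'   `resultant_length`, `histogram` (tibble `bin_start_deg`, `count`) and
#'   the per-event `phases_deg`.
#' @export
phase_accuracy <- function(x, fs, event_times_s) {
  if (length(event_times_s) < 1) stop("no stimulation events")
  idx <- round(event_times_s * fs) + 1
  if (any(idx < 1 | idx > length(x))) stop("events outside the recording")
  d <- apply_zero_phase(ifelse(is.na(x), 0, x), fs, band = c(0.4, 4), order = 2)
  ph <- instantaneous_phase(d)[idx]
  bins <- floor(ph / 5) %% 72
  hist <- tibble::tibble(bin_start_deg = seq(0, 355, by = 5),
                         count = tabulate(bins + 1, nbins = 72))
  structure(list(n = length(ph), mean_deg = circ_mean_deg(ph),
                 sd_deg = circ_sd_deg(ph),
                 resultant_length = circ_resultant(ph),
                 histogram = hist, phases_deg = ph),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("<circular_summary> n = %d, mean = %.1f deg, sd = %.1f deg, R = %.3f\n",
              x$n, x$mean_deg, x$sd_deg, x$resultant_length))
  invisible(x)
}

#' Windowed Pearson correlation between two signals
#'
#' Correlation per non-overlapping window (default 2 s); windows containing
#' NaN in either signal, or flagged bad, are excluded -- detached-electrode
#' segments should not enter the comparison.
#'
#' @param x,y Equal-rate, resynchronized signals of equal length.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, seconds (default 2).
#' @param bad Optional logical vector (per sample) flagging bad signal.
#' @return Tibble with `window_start_s`, `r`, `excluded`.
#' @export
windowed_pearson <- function(x, y, fs, window_s = 2, bad = NULL) {
  if (length(x) != length(y)) stop("signals must have equal length")
  wlen <- round(window_s * fs)
  nw <- floor(length(x) / wlen)
  if (nw == 0) stop("signal shorter than one window")
  idx <- seq_len(nw * wlen)
  X <- matrix(x[idx], wlen); Y <- matrix(y[idx], wlen)
  B <- is.na(X) | is.na(Y)
  if (!is.null(bad)) B <- B | matrix(bad[idx], wlen)
  excl <- colSums(B) > 0
  X[is.na(X)] <- 0; Y[is.na(Y)] <- 0
  mx <- colMeans(X); my <- colMeans(Y)
  cx <- sweep(X, 2, mx); cy <- sweep(Y, 2, my)
  num <- colSums(cx * cy)
  den <- sqrt(colSums(cx^2) * colSums(cy^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  r[excl] <- NA_real_
  tibble::tibble(window_start_s = (seq_len(nw) - 1) * window_s,
                 r = r, excluded = excl)
}
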