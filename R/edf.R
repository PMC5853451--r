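# Minimal EDF (European Data Format) writer/reader: 16-bit samples, one or
# more signals with per-signal sampling rates, 1-s data records. Sufficient
# for the two EEG derivations plus the three accelerometer axes and for
# round-tripping simulator output.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width)   # left-aligned, space-padded
}

#' Write a recording to an EDF file
#'
#' EEG channels are written as "Fp1-M1"/"Fp2-M2" (microvolts), accelerometer
#' axes as "AccX/Y/Z" (g). Samples are quantized to 16-bit over the physical
#' range; the duration is truncated to whole seconds (one data record per
#' second).
#'
#' @param recording An `mc_recording`.
#' @param path Output file path.
#' @param phys_range_uv Physical EEG range (microvolts, symmetric).
#' @param phys_range_g Physical accelerometer range (g, symmetric).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, phys_range_uv = 1000, phys_range_g = 4) {
  stopifnot(inherits(recording, "mc_recording"))
  n_rec <- floor(nrow(recording$eeg) / recording$fs_eeg)
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  labels <- c("Fp1-M1", "Fp2-M2", "AccX", "AccY", "AccZ")
  dims <- c("uV", "uV", "g", "g", "g")
  pmin_ <- c(rep(-phys_range_uv, 2), rep(-phys_range_g, 3))
  pmax_ <- c(rep(phys_range_uv, 2), rep(phys_range_g, 3))
  spr <- c(rep(recording$fs_eeg, 2), rep(recording$fs_accel, 3))
  ns <- 5L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, nchars = width, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (v in labels) wr(v, 16)
  for (i in 1:ns) wr("", 80)
  for (v in dims) wr(v, 8)
  for (v in pmin_) wr(v, 8)
  for (v in pmax_) wr(v, 8)
  for (i in 1:ns) wr(-32768, 8)
  for (i in 1:ns) wr(32767, 8)
  for (i in 1:ns) wr("", 80)
  for (v in spr) wr(v, 8)
  for (i in 1:ns) wr("", 32)
  digitize <- function(x, lo, hi) {
    x <- pmin(pmax(x, lo), hi)
    as.integer(round((x - lo) / (hi - lo) * 65535 - 32768))
  }
  sig <- list(recording$eeg[, 1], recording$eeg[, 2],
              recording$accel[, 1], recording$accel[, 2], recording$accel[, 3])
  dig <- lapply(seq_len(ns), function(i) {
    x <- sig[[i]][seq_len(n_rec * spr[i])]
    if (anyNA(x)) stop("cannot write NA samples to EDF")
    digitize(x, pmin_[i], pmax_[i])
  })
  # interleave per 1-s record
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * spr[i] + 1):(r * spr[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List with `signals` (named list of numeric vectors), `fs` (named
#'   sampling rates), `labels`, `n_records`, `record_duration_s`. If the
#'   channel layout matches [write_edf()]'s, element `recording` holds the
#'   reconstructed `mc_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(1:ns, function(i) rd(16), "")
  for (i in 1:ns) rd(80)
  dims <- vapply(1:ns, function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(1:ns, function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(1:ns, function(i) rd(8), ""))
  dmin <- as.numeric(vapply(1:ns, function(i) rd(8), ""))
  dmax <- as.numeric(vapply(1:ns, function(i) rd(8), ""))
  for (i in 1:ns) rd(80)
  spr <- as.integer(vapply(1:ns, function(i) rd(8), ""))
  for (i in 1:ns) rd(32)
  raw <- lapply(1:ns, function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little", signed = TRUE)
      raw[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- v
    }
  }
  signals <- lapply(1:ns, function(i) {
    (raw[[i]] - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) + pmin_[i]
  })
  names(signals) <- labels
  fs <- stats::setNames(spr / rec_dur, labels)
  out <- list(signals = signals, fs = fs, labels = labels,
              n_records = n_rec, record_duration_s = rec_dur)
  if (identical(labels, c("Fp1-M1", "Fp2-M2", "AccX", "AccY", "AccZ"))) {
    out$recording <- structure(
      list(eeg = cbind(signals[[1]], signals[[2]]),
           accel = cbind(signals[[3]], signals[[4]], signals[[5]]),
           fs_eeg = fs[[1]], fs_accel = fs[[3]], start_time = 0),
      class = "mc_recording")
  }
  out
}
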