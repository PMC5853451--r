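# Plain-text I/O: hypnograms (one stage label per line), event/quality/phase
# CSV tables with a small provenance header, ground-truth CSVs, YAML configs.

#' Write / read a hypnogram text file
#'
#' One stage label (`W`, `N1`, `N2`, `N3`, `REM`) per line; a leading comment
#' records the epoch length.
#'
#' @param hypnogram A `hypnogram`.
#' @param path File path.
#' @return `path` (write) or a `hypnogram` (read).
#' @export
write_hypnogram <- function(hypnogram, path) {
  writeLines(c(sprintf("# epoch_len_s=%g", attr(hypnogram, "epoch_len_s") %||% 30),
               hypnogram$stage), path)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  ln <- readLines(path)
  hdr <- grepl("^#", ln)
  epoch_len <- 30
  m <- regmatches(ln[hdr], regexec("epoch_len_s=([0-9.]+)", ln[hdr]))
  m <- Filter(length, m)
  if (length(m)) epoch_len <- as.numeric(m[[1]][2])
  stages <- trimws(ln[!hdr & nzchar(trimws(ln))])
  bad <- setdiff(unique(stages), stage_levels)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  new_hypnogram(stages, epoch_len)
}

#' Write a tibble as CSV with a provenance header
#'
#' @param df Data frame.
#' @param path File path.
#' @param meta Named character vector written as `# key=value` comment lines.
#' @export
write_table_csv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# socloop %s", utils::packageVersion("socloop")), con)
  for (k in names(meta)) writeLines(sprintf("# %s=%s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Write simulator ground truth as CSV event tables
#'
#' @param truth A `sim_truth`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table_csv(truth$so_events, file.path(dir, "so_events.csv"))
  write_table_csv(truth$artifact_intervals, file.path(dir, "artifact_intervals.csv"))
  write_table_csv(truth$movement_times, file.path(dir, "movements.csv"))
  write_hypnogram(truth$stage_per_epoch, file.path(dir, "hypnogram.txt"))
  invisible(dir)
}

#' Persist / restore a trained model
#'
#' Models are run-time artifacts (forests trained on simulator data) stored
#' with their version stamp.
#'
#' @param model A `quality_model` or `n3_model`.
#' @param path File path (`.rds`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("quality_model", "n3_model")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, c("quality_model", "n3_model"))) stop("not a socloop model file")
  m
}

#' Read / write a run configuration (YAML)
#'
#' Nested sections (`simulator`, `scheduler`, `gates`) configure a run;
#' unknown top-level keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return Named list of sections.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("the yaml package is required")
  cfg <- yaml::read_yaml(path)
  known <- c("simulator", "scheduler", "gates", "seed", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' @rdname read_run_config
#' @param config Named list of sections.
#' @export
write_run_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("the yaml package is required")
  yaml::write_yaml(config, path)
  invisible(path)
}
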