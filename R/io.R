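#' Write / read a recording as CSV
#'
#' The sample stream is written with header
#' `time_s,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z` (UTF-8, '.' decimal
#' separator, six decimals). Annotation events go to a side-car CSV with
#' columns `kind,time_s`, where `kind` is one of `press`, `confirm_start`,
#' `confirm_end`; confirmation starts and ends are paired in file order.
#'
#' @param rec an `fm_recording`.
#' @param path path of the sample CSV.
#' @param events_path path of the events side-car; defaults to
#'   `<path without .csv>_events.csv`.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns an `fm_recording`.
#' @export
write_recording_csv <- function(rec, path,
                                events_path = default_events_path(path)) {
  stopifnot(inherits(rec, "fm_recording"))
  n <- nrow(rec$samples)
  t <- (seq_len(n) - 1) / rec$sample_rate_hz
  df <- data.frame(time_s = sprintf("%.6f", t))
  for (j in seq_along(imu_channels))
    df[[imu_channels[j]]] <- sprintf("%.6f", rec$samples[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  ev <- data.frame(kind = character(0), time_s = character(0))
  if (length(rec$button_presses))
    ev <- rbind(ev, data.frame(kind = "press",
                               time_s = sprintf("%.6f", rec$button_presses)))
  if (nrow(rec$confirmed_intervals)) {
    ci <- rec$confirmed_intervals
    for (i in seq_len(nrow(ci)))
      ev <- rbind(ev,
                  data.frame(kind = c("confirm_start", "confirm_end"),
                             time_s = sprintf("%.6f", ci[i, ])))
  }
  utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_events_path <- function(path)
  paste0(sub("\\.csv$", "", path), "_events.csv")

#' @rdname write_recording_csv
#' @param subject_id subject id to attach to the recording read back.
#' @export
read_recording_csv <- function(path,
                               events_path = default_events_path(path),
                               subject_id = sub("\\.csv$", "", basename(path))) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  expected <- c("time_s", imu_channels)
  if (!identical(header, expected))
    stop(sprintf("parse error in %s, line 1: header must be '%s'",
                 path, paste(expected, collapse = ",")), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, 1L)
  bad <- which(!stats::complete.cases(num))
  if (length(bad))
    stop(sprintf("parse error in %s, line %d: non-numeric cell", path,
                 bad[1] + 1L), call. = FALSE)
  t <- num[, 1]
  if (nrow(num) < 2L || any(diff(t) <= 0))
    stop(sprintf("parse error in %s: time_s must be strictly increasing", path),
         call. = FALSE)
  fs <- round((length(t) - 1) / (t[length(t)] - t[1]), 3)
  presses <- numeric(0)
  intervals <- matrix(numeric(0), 0, 2)
  ev <- utils::read.csv(events_path, colClasses = "character")
  if (!identical(names(ev), c("kind", "time_s")))
    stop(sprintf("parse error in %s, line 1: header must be 'kind,time_s'",
                 events_path), call. = FALSE)
  if (nrow(ev)) {
    tv <- suppressWarnings(as.numeric(ev$time_s))
    bad <- which(is.na(tv) | !ev$kind %in% c("press", "confirm_start",
                                             "confirm_end"))
    if (length(bad))
      stop(sprintf("parse error in %s, line %d: malformed event", events_path,
                   bad[1] + 1L), call. = FALSE)
    presses <- tv[ev$kind == "press"]
    cs <- tv[ev$kind == "confirm_start"]
    ce <- tv[ev$kind == "confirm_end"]
    if (length(cs) != length(ce))
      stop(sprintf("parse error in %s: unpaired confirmation events",
                   events_path), call. = FALSE)
    if (length(cs)) intervals <- cbind(cs, ce)
    dimnames(intervals) <- NULL
  }
  new_recording(subject_id, fs, num[, -1, drop = FALSE], presses, intervals)
}

#' @importFrom stats complete.cases median
NULL

#' Write a cohort manifest
#'
#' Records the file layout, fold assignment and master seed of a cohort in a
#' single structured key-value (YAML) file.
#'
#' @param path output file.
#' @param subject_files named character vector: subject id -> CSV path.
#' @param fold_map data.frame with `subject_id` and `fold`.
#' @param seed master seed used to generate the cohort.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(path, subject_files, fold_map, seed) {
  yaml::write_yaml(list(
    seed = as.integer(seed),
    subjects = as.list(subject_files),
    folds = stats::setNames(as.list(fold_map$fold), fold_map$subject_id)
  ), path)
  invisible(path)
}

#' @importFrom stats setNames
NULL

#' Save / load segments
#'
#' Segment sets are stored as single-file RDS archives carrying the sample
#' tensor, labels, subject ids, provenance flags and the sample rate.
#'
#' @param segments an `fm_segments` object.
#' @param path file path.
#' @return `read_segments` returns the `fm_segments` object.
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "fm_segments"))
  saveRDS(segments, path)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "fm_segments")) stop("not a segment archive", call. = FALSE)
  x
}
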