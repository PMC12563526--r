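#' Segment container
#'
#' An `fm_segments` object holds a set of fixed-length six-channel windows:
#' a `samples` array of dimension `n x window_len x 6`, a `label` factor
#' with levels `FM` / `N-FM`, the source `subject_id`, the ordinal
#' `seg_index` within the session, and `provenance`
#' (`original` / `augmented`). The sample rate is carried as an attribute.
#'
#' @param samples numeric array `n x window_len x 6`.
#' @param label character or factor of segment labels.
#' @param subject_id character vector of subject ids.
#' @param seg_index integer ordinal of each window within its session.
#' @param provenance `original` or `augmented` per segment.
#' @param sample_rate_hz sample rate in Hz.
#' @return an `fm_segments` object.
#' @export
fm_segments <- function(samples, label, subject_id, seg_index,
                        provenance = "original", sample_rate_hz = 190) {
  n <- dim(samples)[1]
  label <- factor(as.character(label), levels = c("FM", "N-FM"))
  stopifnot(length(dim(samples)) == 3L, dim(samples)[3] == 6L,
            length(label) == n, !anyNA(label))
  structure(list(
    samples = samples,
    label = label,
    subject_id = rep_len(as.character(subject_id), n),
    seg_index = rep_len(as.integer(seg_index), n),
    provenance = factor(rep_len(as.character(provenance), n),
                        levels = c("original", "augmented"))
  ), sample_rate_hz = sample_rate_hz, class = "fm_segments")
}

#' @export
length.fm_segments <- function(x) dim(x$samples)[1]

#' @export
`[.fm_segments` <- function(x, i) {
  fm_segments(x$samples[i, , , drop = FALSE], x$label[i], x$subject_id[i],
              x$seg_index[i], x$provenance[i],
              attr(x, "sample_rate_hz"))
}

#' Concatenate segment sets
#' @param ... `fm_segments` objects with identical window geometry.
#' @return a single `fm_segments` object.
#' @export
bind_segments <- function(...) {
  xs <- list(...)
  xs <- xs[!vapply(xs, is.null, logical(1))]
  stopifnot(length(xs) > 0L)
  if (length(xs) == 1L) return(xs[[1]])
  wl <- unique(vapply(xs, function(x) dim(x$samples)[2], integer(1)))
  stopifnot(length(wl) == 1L)
  n <- sum(vapply(xs, length, integer(1)))
  samples <- array(0, c(n, wl, 6L))
  at <- 0L
  for (x in xs) {
    samples[at + seq_len(length(x)), , ] <- x$samples
    at <- at + length(x)
  }
  fm_segments(samples,
              unlist(lapply(xs, function(x) as.character(x$label))),
              unlist(lapply(xs, `[[`, "subject_id")),
              unlist(lapply(xs, `[[`, "seg_index")),
              unlist(lapply(xs, function(x) as.character(x$provenance))),
              attr(xs[[1]], "sample_rate_hz"))
}

#' @export
print.fm_segments <- function(x, ...) {
  cat(sprintf("<fm_segments> %d segments (%d FM / %d N-FM), window %d samples, %d subjects\n",
              length(x), sum(x$label == "FM"), sum(x$label == "N-FM"),
              dim(x$samples)[2], length(unique(x$subject_id))))
  invisible(x)
}

#' Segment a recording into labeled 5 s windows
#'
#' Cuts the recording into non-overlapping windows of `window_s` seconds
#' (`floor(duration / window_s)` of them) and applies dual-confirmation
#' labeling: a window is `FM` iff it overlaps an ultrasound-confirmed
#' interval by at least `min_overlap_s` seconds AND a button press lies
#' within `coincidence_tol_s` of that interval; all other windows are
#' `N-FM`.
#'
#' @param rec an `fm_recording`.
#' @param window_s window length in seconds.
#' @param coincidence_tol_s press-to-interval coincidence tolerance (s).
#' @param min_overlap_s minimum window/interval overlap (s) for a window to
#'   count as covering the interval; avoids boundary flicker.
#' @return an `fm_segments` object with `provenance = "original"`.
#' @export
segment_and_label <- function(rec, window_s = 5, coincidence_tol_s = 2.0,
                              min_overlap_s = 0.5) {
  stopifnot(inherits(rec, "fm_recording"), window_s > 0)
  fs <- rec$sample_rate_hz
  wl <- round(window_s * fs)
  n_win <- floor(nrow(rec$samples) / wl)
  if (n_win < 1L) stop("recording shorter than one window", call. = FALSE)

  # confirmed intervals that carry a coincident press
  ci <- rec$confirmed_intervals
  confirmed <- logical(nrow(ci))
  for (i in seq_len(nrow(ci))) {
    d <- pmax(0, pmax(ci[i, 1] - rec$button_presses,
                      rec$button_presses - ci[i, 2]))
    confirmed[i] <- length(d) > 0 && any(d <= coincidence_tol_s)
  }
  ci <- ci[confirmed, , drop = FALSE]

  samples <- array(0, c(n_win, wl, 6L))
  label <- rep("N-FM", n_win)
  for (w in seq_len(n_win)) {
    i0 <- (w - 1L) * wl
    samples[w, , ] <- rec$samples[i0 + seq_len(wl), ]
    ws <- i0 / fs
    we <- ws + window_s
    if (nrow(ci)) {
      ov <- pmin(we, ci[, 2]) - pmax(ws, ci[, 1])
      if (any(ov >= min_overlap_s)) label[w] <- "FM"
    }
  }
  fm_segments(samples, label, rec$subject_id, seq_len(n_win),
              "original", fs)
}

#' Subject-independent split specification
#'
#' @param test_fraction fraction of subjects assigned to the test fold.
#' @param validation_fraction_of_train fraction of the remaining subjects
#'   assigned to validation.
#' @param seed seed for the random subject assignment (ignored when a
#'   registered `fold_map` is supplied to the splitter).
#' @return an object of class `fm_split_spec`.
#' @export
split_spec <- function(test_fraction = 0.20,
                       validation_fraction_of_train = 0.20, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            validation_fraction_of_train > 0,
            validation_fraction_of_train < 1)
  structure(list(test_fraction = test_fraction,
                 validation_fraction_of_train = validation_fraction_of_train,
                 seed = seed), class = "fm_split_spec")
}

#' Split segments by subject into train / validation / test
#'
#' Partitions segments at the subject level so no subject contributes to
#' more than one fold. With a registered `fold_map` the assignment is taken
#' verbatim; otherwise `round(test_fraction * n)` subjects (at least one)
#' are drawn for test and, of the remainder,
#' `round(validation_fraction_of_train * m)` (at least one) for validation.
#'
#' @param segments an `fm_segments` object.
#' @param spec an [split_spec()].
#' @param fold_map optional data.frame with columns `subject_id`, `fold`
#'   (values among train/validation/test) taken verbatim.
#' @return named list of `fm_segments`: `train`, `validation`, `test`.
#' @export
split_subject_independent <- function(segments, spec = split_spec(),
                                      fold_map = NULL) {
  stopifnot(inherits(segments, "fm_segments"))
  subjects <- unique(segments$subject_id)
  if (is.null(fold_map)) {
    if (length(subjects) < 3L)
      stop("need at least 3 subjects for a three-way split", call. = FALSE)
    n <- length(subjects)
    n_test <- max(1L, round(spec$test_fraction * n))
    with_seed(spec$seed, {
      test_s <- sample(subjects, n_test)
      rest <- setdiff(subjects, test_s)
      n_val <- max(1L, round(spec$validation_fraction_of_train * length(rest)))
      val_s <- sample(rest, n_val)
    })
    fold_map <- data.frame(
      subject_id = subjects,
      fold = ifelse(subjects %in% test_s, "test",
                    ifelse(subjects %in% val_s, "validation", "train")),
      stringsAsFactors = FALSE)
  } else {
    if (anyDuplicated(fold_map$subject_id))
      stop("fold_map lists a subject in more than one fold", call. = FALSE)
    missing <- setdiff(subjects, fold_map$subject_id)
    if (length(missing))
      stop("fold_map missing subjects: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  fold <- fold_map$fold[match(segments$subject_id, fold_map$subject_id)]
  out <- list(train = segments[fold == "train"],
              validation = segments[fold == "validation"],
              test = segments[fold == "test"])
  # leakage guard: folds must have pairwise-disjoint subject sets
  ss <- lapply(out, function(x) unique(x$subject_id))
  if (length(intersect(ss$train, ss$validation)) ||
      length(intersect(ss$train, ss$test)) ||
      length(intersect(ss$validation, ss$test)))
    stop("internal error: subject appears in more than one fold")
  out
}
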