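#' Merge six IMU channels into three axis channels
#'
#' For each spatial axis i in {x, y, z}, the merged channel is
#' `zscore(accel_i) + zscore(gyro_i)`, computed per segment. Z-scoring each
#' series before summation removes inter-sensor amplitude differences (the
#' two sensors have different physical units) while preserving per-axis
#' directionality. A zero-variance channel contributes the zero series.
#'
#' @param seg a `window_len x 6` matrix (columns acc_x..gyr_z) or an
#'   `fm_segments` object of length 1.
#' @return `window_len x 3` matrix.
#' @export
merge_axes <- function(seg) {
  if (inherits(seg, "fm_segments")) {
    stopifnot(length(seg) == 1L)
    seg <- seg$samples[1, , ]
  }
  stopifnot(is.matrix(seg), ncol(seg) == 6L)
  z <- zscore_cols(seg)
  z[, 1:3] + z[, 4:6]
}

#' Log-magnitude STFT of one channel
#'
#' Frames the series with a Hamming window of `window` samples advanced by
#' `window * (1 - overlap)` samples (no zero-padding or centering; a final
#' partial frame is dropped), takes the magnitude of the windowed DFT and
#' converts it to decibels as `20 * log10(|X| + eps)`.
#'
#' @param x numeric series of length >= `window`.
#' @param window window length in samples.
#' @param overlap fractional overlap between adjacent frames.
#' @param sample_rate_hz sample rate (Hz) used only for the frequency/time
#'   axes attached as attributes.
#' @param eps additive floor inside the logarithm.
#' @return `(window/2 + 1) x n_frames` matrix of dB magnitudes with
#'   attributes `bin_freqs` (Hz) and `frame_times` (s);
#'   `n_frames = 1 + floor((length(x) - window) / hop)`.
#' @export
stft_log <- function(x, window = 256L, overlap = 0.5, sample_rate_hz = 190,
                     eps = 1e-8) {
  n <- length(x)
  window <- as.integer(window)
  if (n < window)
    stop("series shorter than the STFT window", call. = FALSE)
  hop <- as.integer(round(window * (1 - overlap)))
  n_frames <- 1L + (n - window) %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop
  w <- signal::hamming(window)
  frames <- vapply(starts, function(s) x[s + seq_len(window)] * w,
                   numeric(window))
  X <- stats::mvfft(frames)
  nb <- window %/% 2L + 1L
  mag <- Mod(X[seq_len(nb), , drop = FALSE])
  out <- 20 * log10(mag + eps)
  attr(out, "bin_freqs") <- (seq_len(nb) - 1L) * sample_rate_hz / window
  attr(out, "frame_times") <- (starts + window / 2) / sample_rate_hz
  out
}

#' Global normalization statistics
#'
#' Pooled mean and standard deviation over every cell of the training
#' spectrograms. Fitted on the training split only and then applied
#' verbatim to validation and test data, so no information leaks across
#' splits.
#'
#' @param spectrograms an array of spectrogram values (any shape; the batch
#'   array from [spectrogram_batch()] or a list of `fm_spectrogram`).
#' @param fitted_on identifier of the split the statistics come from.
#' @return object of class `fm_norm_stats` with `global_mean`, `global_sd`,
#'   `fitted_on`.
#' @export
fit_global_stats <- function(spectrograms, fitted_on = "train") {
  if (is.list(spectrograms) && !is.array(spectrograms))
    spectrograms <- unlist(lapply(spectrograms, function(s)
      as.vector(if (inherits(s, "fm_spectrogram")) s$values else s)))
  v <- as.vector(spectrograms)
  if (!length(v)) stop("empty training split", call. = FALSE)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("zero pooled variance: cannot fit global statistics", call. = FALSE)
  structure(list(global_mean = mean(v), global_sd = s,
                 fitted_on = fitted_on), class = "fm_norm_stats")
}

#' @export
print.fm_norm_stats <- function(x, ...) {
  cat(sprintf("<fm_norm_stats> mean %.4f, sd %.4f (fitted on %s)\n",
              x$global_mean, x$global_sd, x$fitted_on))
  invisible(x)
}

#' @rdname fit_global_stats
#' @param stats an `fm_norm_stats` object.
#' @param path file path for the YAML round trip.
#' @export
write_norm_stats <- function(stats, path) {
  yaml::write_yaml(unclass(stats), path, precision = 17L)
  invisible(path)
}

#' @rdname fit_global_stats
#' @export
read_norm_stats <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(global_mean = as.numeric(x$global_mean),
                 global_sd = as.numeric(x$global_sd),
                 fitted_on = x$fitted_on), class = "fm_norm_stats")
}

#' Transform one segment into a 3-channel log-spectrogram
#'
#' Pipeline: per-segment z-scoring of the raw channels (inside
#' [merge_axes()]), axis-pair merging to three channels, [stft_log()] per
#' merged channel, then optional global standardization with training-split
#' statistics.
#'
#' @param seg `window_len x 6` matrix or length-1 `fm_segments`.
#' @param stats optional `fm_norm_stats`; when given, values are
#'   standardized as `(x - global_mean) / global_sd`.
#' @param sample_rate_hz sample rate (Hz).
#' @param window,overlap STFT parameters, see [stft_log()].
#' @return object of class `fm_spectrogram`: list with `values`
#'   (3 x n_bins x n_frames array), `bin_freqs`, `frame_times`.
#' @export
transform_segment <- function(seg, stats = NULL, sample_rate_hz = 190,
                              window = 256L, overlap = 0.5, eps = 1e-8) {
  merged <- merge_axes(seg)
  n <- nrow(merged)
  window <- as.integer(window)
  if (n < window) stop("series shorter than the STFT window", call. = FALSE)
  hop <- as.integer(round(window * (1 - overlap)))
  nf <- 1L + (n - window) %/% hop
  starts <- (seq_len(nf) - 1L) * hop
  # gather every frame of every merged channel and run one FFT batch;
  # identical arithmetic to stft_log() per channel
  idx <- outer(seq_len(window), starts, "+")
  w <- signal::hamming(window)
  frames <- matrix(0, window, nf * 3L)
  for (ch in 1:3)
    frames[, (ch - 1L) * nf + seq_len(nf)] <- merged[idx, ch] * w
  X <- stats::mvfft(frames)
  nb <- window %/% 2L + 1L
  db <- 20 * log10(Mod(X[seq_len(nb), , drop = FALSE]) + eps)
  vals <- array(0, c(3L, nb, nf))
  for (ch in 1:3)
    vals[ch, , ] <- db[, (ch - 1L) * nf + seq_len(nf)]
  if (!is.null(stats)) {
    stopifnot(inherits(stats, "fm_norm_stats"))
    vals <- (vals - stats$global_mean) / stats$global_sd
  }
  structure(list(values = vals,
                 bin_freqs = (seq_len(nb) - 1L) * sample_rate_hz / window,
                 frame_times = (starts + window / 2) / sample_rate_hz),
            class = "fm_spectrogram")
}

#' @export
print.fm_spectrogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<fm_spectrogram> %d channels x %d bins x %d frames\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Batch-transform segments into a model-input array
#'
#' @param segments an `fm_segments` object.
#' @param stats optional `fm_norm_stats` applied to every spectrogram.
#' @param window,overlap STFT parameters.
#' @return numeric array `n x n_bins x n_frames x 3` (batch, frequency,
#'   time, channel) with `labels` attached as an attribute when present.
#' @export
spectrogram_batch <- function(segments, stats = NULL, window = 256L,
                              overlap = 0.5) {
  stopifnot(inherits(segments, "fm_segments"))
  fs <- attr(segments, "sample_rate_hz")
  n <- length(segments)
  first <- transform_segment(segments$samples[1, , ], stats, fs, window,
                             overlap)
  d <- dim(first$values)
  out <- array(0, c(n, d[2], d[3], 3L))
  put <- function(i, v) for (ch in 1:3) out[i, , , ch] <<- v[ch, , ]
  put(1L, first$values)
  if (n > 1) for (i in 2:n)
    put(i, transform_segment(segments$samples[i, , ], stats, fs, window,
                             overlap)$values)
  attr(out, "labels") <- segments$label
  attr(out, "bin_freqs") <- first$bin_freqs
  attr(out, "frame_times") <- first$frame_times
  out
}
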