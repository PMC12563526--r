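# shared builders and oracles for the test suite

# small cohort configuration without spurious annotation noise
quiet_config <- function(duration_s = 100, ...) {
  fm_cohort_config(session_duration_s = duration_s,
                   spurious_press_rate = 0,
                   unpaired_confirm_rate = 0, ...)
}

# hand-built recording for labeling oracles
make_recording <- function(duration_s, presses = numeric(0),
                           intervals = matrix(numeric(0), 0, 2),
                           fs = 190, subject_id = "T01") {
  n <- round(duration_s * fs)
  fm_recording(subject_id, fs, matrix(stats::rnorm(n * 6, sd = 0.01), n, 6),
               presses, intervals)
}

# deterministic small segment set with given labels
make_segments <- function(n, label = "FM", wl = 950, subject = "S1",
                          seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(fm_segments(array(stats::rnorm(n * wl * 6), c(n, wl, 6)),
                         rep_len(label, n), subject, seq_len(n)))
}

# naive windowed-DFT oracle for one STFT frame (independent of stft_log)
naive_frame_dft <- function(frame) {
  n <- length(frame)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)) # Hamming
  xw <- frame * w
  nb <- n %/% 2 + 1
  vapply(seq_len(nb), function(k) {
    f <- k - 1
    Mod(sum(xw * exp(-2i * pi * f * (0:(n - 1)) / n)))
  }, numeric(1))
}

# 1-20 Hz accelerometer band energy of one segment (FFT-mask oracle)
band_energy <- function(seg_mat, fs = 190, band = c(1, 20)) {
  X <- stats::mvfft(seg_mat[, 1:3])
  n <- nrow(seg_mat)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  sum(Mod(X[f >= band[1] & f <= band[2], ])^2) / n
}

# active rotation matrix of a unit quaternion (standard formula; the
# package's conjugation uses the inverse-on-left convention = transpose)
quat_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# tiny, quickly trainable model spec (quarter-width inverted-residual)
tiny_spec <- function(dropout = 0.2)
  fm_model_spec("student_inverted_residual", width_multiplier = 0.25,
                dropout = dropout)

# linearly separable toy spectrogram data: FM segments carry a strong
# positive block in low frequency bins, N-FM a negative one
toy_spectro_data <- function(n, seed = 1) {
  set.seed(seed)
  x <- array(stats::rnorm(n * 129 * 6 * 3, sd = 0.5), c(n, 129, 6, 3))
  lab <- rep(c("FM", "N-FM"), length.out = n)
  for (i in seq_len(n))
    x[i, 5:30, , ] <- x[i, 5:30, , ] + if (lab[i] == "FM") 2 else -2
  attr(x, "labels") <- factor(lab, levels = c("FM", "N-FM"))
  x
}

# environment-level cache so expensive cohort artefacts are built once
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}
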