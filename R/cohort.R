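#' Configuration for a synthetic IMU cohort
#'
#' Describes the statistical structure of a synthetic cohort of abdominal
#' six-axis IMU recordings: session geometry, fetal-movement (FM) burst
#' characteristics, maternal-motion artifacts and sensor noise. Defaults
#' emulate a 120-subject study protocol: ~23.5 min sessions sampled at
#' 190 Hz, segmented into non-overlapping 5 s windows, with roughly 3.2% of
#' windows containing a dual-confirmed FM event.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param session_duration_s session length in seconds. The default gives an
#'   average of about 282 five-second windows per subject.
#' @param sample_rate_hz IMU sample rate in Hz.
#' @param fm_prevalence fraction of 5 s windows containing an FM event; must
#'   lie in (0, 0.5).
#' @param fm_burst_duration_s length-2 range (s) of FM burst durations.
#' @param fm_band_hz length-2 frequency band (Hz) carrying FM burst energy.
#' @param fm_snr_db segment-level signal-to-background ratio in dB: a 5 s
#'   window carrying an FM burst holds about `10^(fm_snr_db/10)` times the
#'   in-band (`fm_band_hz`) energy of the same window without it. 12 dB
#'   (default) corresponds to clearly perceptible movements; 6 dB is an
#'   easy-to-moderate setting; near 0 dB bursts drown in the background.
#' @param maternal_artifact_rate maternal-motion artifacts per minute
#'   (slow high-amplitude excursions and occasional posture-shift steps).
#' @param noise_sd accelerometer white-noise standard deviation in g; the
#'   gyroscope noise is `noise_sd * gyro_unit_scale` in deg/s.
#' @param drift_sd slow baseline-drift amplitude in g.
#' @param gyro_unit_scale deg/s of gyroscope signal per g of accelerometer
#'   signal for coupled components.
#' @param spurious_press_rate button presses per minute with no ultrasound
#'   confirmation (maternal perception errors).
#' @param unpaired_confirm_rate ultrasound-confirmed movement intervals per
#'   minute that the mother did not perceive (no button press); these carry
#'   a weak movement burst 8 dB below `fm_snr_db`.
#' @param press_delay_mean_s,press_delay_sd_s,press_delay_max_s maternal
#'   reaction delay model: Gaussian(mean, sd) clamped to
#'   `[0, press_delay_max_s]` seconds after burst onset.
#' @param window_s segmentation window length in seconds.
#' @param seed optional integer seed stored with the configuration.
#'
#' @return an object of class `fm_cohort_config` (a validated list).
#' @export
fm_cohort_config <- function(n_subjects = 120L,
                             session_duration_s = 1412.5,
                             sample_rate_hz = 190,
                             fm_prevalence = 1073 / 33843,
                             fm_burst_duration_s = c(0.5, 2.0),
                             fm_band_hz = c(1, 20),
                             fm_snr_db = 12,
                             maternal_artifact_rate = 2,
                             noise_sd = 0.02,
                             drift_sd = 0.01,
                             gyro_unit_scale = 50,
                             spurious_press_rate = 0.3,
                             unpaired_confirm_rate = 0.2,
                             press_delay_mean_s = 0.8,
                             press_delay_sd_s = 0.4,
                             press_delay_max_s = 2.0,
                             window_s = 5,
                             seed = NULL) {
  for (nm in c("n_subjects", "session_duration_s", "sample_rate_hz",
               "maternal_artifact_rate", "noise_sd", "drift_sd",
               "gyro_unit_scale", "press_delay_mean_s", "press_delay_sd_s",
               "press_delay_max_s", "window_s"))
    stopifnot_scalar_pos(get(nm), nm)
  if (!(fm_prevalence > 0 && fm_prevalence < 0.5))
    stop("fm_prevalence must lie in (0, 0.5)", call. = FALSE)
  if (length(fm_burst_duration_s) != 2L || any(fm_burst_duration_s <= 0) ||
      diff(fm_burst_duration_s) < 0)
    stop("fm_burst_duration_s must be an increasing positive range", call. = FALSE)
  if (length(fm_band_hz) != 2L || any(fm_band_hz <= 0) ||
      fm_band_hz[2] <= fm_band_hz[1] || fm_band_hz[2] >= sample_rate_hz / 2)
    stop("fm_band_hz must be an increasing band below Nyquist", call. = FALSE)
  if (spurious_press_rate < 0 || unpaired_confirm_rate < 0)
    stop("event rates must be non-negative", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    session_duration_s = session_duration_s,
    sample_rate_hz = sample_rate_hz,
    fm_prevalence = fm_prevalence,
    fm_burst_duration_s = fm_burst_duration_s,
    fm_band_hz = fm_band_hz,
    fm_snr_db = fm_snr_db,
    maternal_artifact_rate = maternal_artifact_rate,
    noise_sd = noise_sd,
    drift_sd = drift_sd,
    gyro_unit_scale = gyro_unit_scale,
    spurious_press_rate = spurious_press_rate,
    unpaired_confirm_rate = unpaired_confirm_rate,
    press_delay_mean_s = press_delay_mean_s,
    press_delay_sd_s = press_delay_sd_s,
    press_delay_max_s = press_delay_max_s,
    window_s = window_s,
    seed = seed
  ), class = "fm_cohort_config")
}

imu_channels <- c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")

new_recording <- function(subject_id, sample_rate_hz, samples,
                          button_presses, confirmed_intervals) {
  colnames(samples) <- imu_channels
  if (!all(is.finite(samples))) stop("recording samples must be finite")
  if (length(confirmed_intervals)) {
    ci <- confirmed_intervals
    dur <- nrow(samples) / sample_rate_hz
    if (any(ci[, 1] >= ci[, 2]) || any(ci[, 1] < 0) || any(ci[, 2] > dur))
      stop("confirmed intervals must satisfy start < end within the session")
  }
  structure(list(
    subject_id = subject_id,
    sample_rate_hz = sample_rate_hz,
    samples = samples,
    button_presses = sort(button_presses),
    confirmed_intervals = confirmed_intervals[order(confirmed_intervals[, 1]), ,
                                              drop = FALSE]
  ), class = "fm_recording")
}

#' Construct a recording object
#'
#' Builds an `fm_recording` from raw components, validating that samples
#' are finite and that confirmed intervals satisfy `start < end` inside the
#' session. Useful for assembling recordings from external sources.
#'
#' @param subject_id subject identifier.
#' @param sample_rate_hz sample rate in Hz.
#' @param samples numeric `n x 6` matrix (acc_x..acc_z in g,
#'   gyr_x..gyr_z in deg/s).
#' @param button_presses numeric vector of press times (s).
#' @param confirmed_intervals `m x 2` matrix of interval start/end times (s).
#' @return an `fm_recording`.
#' @export
fm_recording <- function(subject_id, sample_rate_hz, samples,
                         button_presses = numeric(0),
                         confirmed_intervals = matrix(numeric(0), 0, 2)) {
  stopifnot(is.matrix(samples), ncol(samples) == 6L)
  new_recording(subject_id, sample_rate_hz, samples, button_presses,
                confirmed_intervals)
}

#' @export
print.fm_recording <- function(x, ...) {
  cat(sprintf("<fm_recording> subject %s: %.1f s @ %g Hz, %d presses, %d confirmed intervals\n",
              x$subject_id, nrow(x$samples) / x$sample_rate_hz,
              x$sample_rate_hz, length(x$button_presses),
              nrow(x$confirmed_intervals)))
  invisible(x)
}

# band-limited RMS via an FFT mask; x is a matrix (samples x channels)
bandpass_rms <- function(x, fs, band) {
  n <- nrow(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # absolute frequency of each DFT bin
  keep <- f >= band[1] & f <= band[2]
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  y <- Re(stats::mvfft(X, inverse = TRUE)) / n
  sqrt(mean(y^2))
}

rand_unit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# damped-sinusoid burst with unit RMS; accelerometer columns 1:3 and
# phase-coupled gyroscope columns 4:6 each have unit RMS before scaling
make_burst <- function(len, fs, band) {
  ncomp <- sample(2:4, 1)
  t <- (seq_len(len) - 1) / fs
  tau <- (len / fs) / 3
  acc <- matrix(0, len, 3)
  gyr <- matrix(0, len, 3)
  for (i in seq_len(ncomp)) {
    f <- stats::runif(1, band[1], band[2])
    ph <- stats::runif(1, 0, 2 * pi)
    env <- exp(-t / tau)
    w <- env * sin(2 * pi * f * t + ph)
    wg <- env * sin(2 * pi * f * t + ph + pi / 2) # quarter-cycle lag
    acc <- acc + outer(w, rand_unit3())
    gyr <- gyr + outer(wg, rand_unit3())
  }
  acc <- acc / max(sqrt(mean(acc^2)), 1e-12)
  gyr <- gyr / max(sqrt(mean(gyr^2)), 1e-12)
  cbind(acc, gyr)
}

# smooth low-frequency maternal-motion background: white noise + slow drift +
# artifact bumps/steps. Returns samples x 6 matrix (accel in g, gyro deg/s).
make_background <- function(n, fs, cfg) {
  gsc <- cfg$gyro_unit_scale
  sdv <- rep(c(cfg$noise_sd, cfg$noise_sd * gsc), each = 3)
  x <- matrix(stats::rnorm(n * 6), n, 6)
  x <- sweep(x, 2, sdv, "*")
  x[, 3] <- x[, 3] + 1 # gravity baseline on the z accelerometer
  t <- (seq_len(n) - 1) / fs
  for (ch in 1:6) {
    amp <- if (ch <= 3) cfg$drift_sd else cfg$drift_sd * gsc
    for (i in 1:2) {
      f <- stats::runif(1, 0.005, 0.05)
      x[, ch] <- x[, ch] + amp * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
  }
  dur <- n / fs
  n_art <- stats::rpois(1, cfg$maternal_artifact_rate * dur / 60)
  for (i in seq_len(n_art)) {
    kind <- sample(c("bump", "step"), 1, prob = c(0.8, 0.2))
    amp_a <- stats::runif(1, 5, 15) * cfg$noise_sd
    load_a <- rand_unit3()
    load_g <- rand_unit3()
    if (kind == "bump") {
      bl <- min(round(stats::runif(1, 3, 8) * fs), n - 1L)
      s0 <- sample.int(max(1L, n - bl), 1)
      idx <- s0:(s0 + bl - 1L)
      fl <- stats::runif(1, 0.05, 0.4) # well below the 1 Hz band edge
      shape <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = bl))) *
        sin(2 * pi * fl * (idx / fs))
      x[idx, 1:3] <- x[idx, 1:3] + amp_a * outer(shape, load_a)
      x[idx, 4:6] <- x[idx, 4:6] + amp_a * gsc * outer(shape, load_g)
    } else {
      # posture shift: offset reached through a ~1.5 s raised-cosine ramp
      s0 <- sample.int(n, 1)
      amp_s <- stats::runif(1, 3, 8) * cfg$noise_sd
      rl <- min(round(1.5 * fs), n - s0 + 1L)
      ramp <- c(0.5 * (1 - cos(pi * seq(0, 1, length.out = rl))),
                rep(1, n - s0 + 1L - rl))
      x[s0:n, 1:3] <- x[s0:n, 1:3, drop = FALSE] +
        outer(ramp, amp_s * load_a)
    }
  }
  x
}

#' Generate one synthetic IMU recording
#'
#' Simulates a single subject session: band-limited FM bursts (damped
#' sinusoids with random axis loading, the gyroscope phase-coupled to the
#' accelerometer) superimposed on a maternal-motion background, with the
#' dual-confirmation annotation stream (button presses and
#' ultrasound-confirmed intervals). Exactly `n_fm_events` confirmed intervals
#' are paired with a press inside the coincidence tolerance; additional
#' spurious presses and unpaired confirmations are injected at the configured
#' rates and placed so they can never satisfy dual confirmation.
#'
#' @param config an [fm_cohort_config()].
#' @param subject_id subject identifier string.
#' @param n_fm_events number of dual-confirmed FM events to embed.
#' @param seed integer seed; the same `(config, seed)` pair reproduces the
#'   recording exactly.
#' @return an `fm_recording`: list with `subject_id`, `sample_rate_hz`,
#'   `samples` (n x 6 matrix, accel in g / gyro in deg/s), `button_presses`
#'   (seconds) and `confirmed_intervals` (m x 2 matrix of start/end seconds).
#' @export
generate_recording <- function(config, subject_id = "S001", n_fm_events = NULL,
                               seed = 1L) {
  stopifnot(inherits(config, "fm_cohort_config"))
  fs <- config$sample_rate_hz
  w <- config$window_s
  n <- round(config$session_duration_s * fs)
  n_windows <- floor(n / (w * fs))
  if (n_windows < 1L) stop("session shorter than one window", call. = FALSE)
  with_seed(seed, {
    if (is.null(n_fm_events))
      n_fm_events <- stats::rbinom(1, n_windows, config$fm_prevalence)
    if (n_fm_events > n_windows)
      stop(sprintf("cannot place %d non-overlapping FM events in %d windows",
                   n_fm_events, n_windows), call. = FALSE)
    fm_win <- sort(sample.int(n_windows, n_fm_events))

    # unpaired confirmations must sit >= 2 windows from any press-carrying
    # window so no press can fall within the coincidence tolerance
    blocked <- unique(as.vector(outer(fm_win, -2:2, "+")))
    cand_uc <- setdiff(seq_len(n_windows), blocked)
    dur_min <- n / fs / 60
    n_uc <- min(stats::rpois(1, config$unpaired_confirm_rate * dur_min),
                length(cand_uc))
    uc_win <- sort(cand_uc[sample.int(length(cand_uc), n_uc)])
    blocked2 <- unique(c(blocked, as.vector(outer(uc_win, -2:2, "+"))))
    cand_sp <- setdiff(seq_len(n_windows), blocked2)
    n_sp <- min(stats::rpois(1, config$spurious_press_rate * dur_min),
                length(cand_sp))
    sp_win <- sort(cand_sp[sample.int(length(cand_sp), n_sp)])

    x <- make_background(n, fs, config)

    place_burst <- function(win, snr_db) {
      blen_s <- stats::runif(1, config$fm_burst_duration_s[1],
                             config$fm_burst_duration_s[2])
      ws <- (win - 1) * w
      onset <- ws + stats::runif(1, 0.05, w - 0.1 - blen_s)
      i0 <- round(onset * fs) + 1L
      bl <- round(blen_s * fs)
      idx <- i0:(i0 + bl - 1L)
      wrows <- (win - 1L) * round(w * fs) + seq_len(round(w * fs))
      burst <- make_burst(bl, fs, config$fm_band_hz)
      # snr_db is the segment-level in-band energy ratio: a window carrying
      # the burst holds ~10^(snr/10) times the band energy of the bare
      # background window, so the burst RMS over its duration is
      # sqrt((10^(snr/10) - 1) * window_len / burst_len) x background RMS
      gain <- sqrt(max(10^(snr_db / 10) - 1, 0) * length(wrows) / bl)
      rms_a <- bandpass_rms(x[wrows, 1:3, drop = FALSE], fs, config$fm_band_hz)
      rms_g <- bandpass_rms(x[wrows, 4:6, drop = FALSE], fs, config$fm_band_hz)
      x[idx, 1:3] <<- x[idx, 1:3] + gain * rms_a * burst[, 1:3]
      x[idx, 4:6] <<- x[idx, 4:6] + gain * rms_g * burst[, 4:6]
      c(onset, onset + blen_s)
    }

    intervals <- matrix(numeric(0), 0, 2)
    presses <- numeric(0)
    for (win in fm_win) {
      iv <- place_burst(win, config$fm_snr_db)
      delay <- min(max(stats::rnorm(1, config$press_delay_mean_s,
                                    config$press_delay_sd_s), 0),
                   config$press_delay_max_s)
      presses <- c(presses, min(iv[1] + delay, n / fs - 1e-3))
      intervals <- rbind(intervals, iv)
    }
    for (win in uc_win)
      intervals <- rbind(intervals, place_burst(win, config$fm_snr_db - 8))
    for (win in sp_win)
      presses <- c(presses, (win - 1) * w + stats::runif(1, 0.5, w - 0.5))

    dimnames(intervals) <- NULL
    new_recording(subject_id, fs, x, presses, intervals)
  })
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject FM event counts from a binomial with the configured
#' prevalence and generates one recording per subject under derived
#' sub-seeds, so the whole cohort is reproducible from `(config, seed)`.
#'
#' @param config an [fm_cohort_config()].
#' @param seed master integer seed.
#' @return list of `fm_recording` objects, one per subject.
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "fm_cohort_config"))
  seeds <- derive_seeds(seed, config$n_subjects)
  lapply(seq_len(config$n_subjects), function(i) {
    generate_recording(config, sprintf("S%03d", i), n_fm_events = NULL,
                       seed = seeds[i])
  })
}
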