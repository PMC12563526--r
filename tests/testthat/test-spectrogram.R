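test_that("axis-pair merging follows the zscore-sum rule", {
  set.seed(1)
  acc <- matrix(rnorm(950 * 3), 950, 3)
  # constant gyroscope contributes the zero series
  seg <- cbind(acc, matrix(5, 950, 3))
  z <- scale(acc)
  attr(z, "scaled:center") <- NULL
  expect_equal(unname(merge_axes(seg)), unname(z[, 1:3]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical accel and gyro series double the z-score
  seg2 <- cbind(acc, acc)
  expect_equal(unname(merge_axes(seg2)), 2 * unname(z[, 1:3]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # merged channels are zero-mean per segment
  seg3 <- matrix(rnorm(950 * 6), 950, 6)
  expect_equal(colMeans(merge_axes(seg3)), rep(0, 3), tolerance = 1e-10)
})

test_that("STFT geometry matches the frame-count formula", {
  x <- rnorm(950)
  S <- stft_log(x)
  expect_equal(dim(S), c(129, 6))
  expect_equal(attr(S, "bin_freqs")[1], 0)
  expect_equal(attr(S, "bin_freqs")[129], 190 / 2)
  expect_error(stft_log(rnorm(100)), "shorter")
  # generic formula on other lengths
  for (n in c(256, 300, 512, 1000))
    expect_equal(ncol(stft_log(rnorm(n))), 1 + floor((n - 256) / 128))
})

test_that("a constant series concentrates its energy at the DC bin", {
  S <- stft_log(rep(2, 950))
  for (f in 1:6) {
    expect_equal(which.max(S[, f]), 1)
    # outside the Hamming main lobe (+/- 2 bins) everything is > 40 dB down
    expect_lt(max(S[4:129, f]), S[1, f] - 40)
  }
})

test_that("a bin-centred sinusoid peaks at its bin in every frame", {
  fs <- 190
  f0 <- 20 * fs / 256 # exactly bin 21
  x <- sin(2 * pi * f0 * (0:949) / fs)
  S <- stft_log(x)
  expect_equal(unname(apply(S, 2, which.max)), rep(21L, 6))
})

test_that("STFT magnitudes match a naive windowed-DFT oracle", {
  set.seed(2)
  x <- rnorm(950)
  S <- stft_log(x)
  mag <- 10^(S / 20) - 1e-8
  for (f in c(1, 3, 6)) {
    frame <- x[(f - 1) * 128 + 1:256]
    expect_equal(mag[, f], naive_frame_dft(frame), tolerance = 1e-6)
  }
})

test_that("global statistics are fitted on train only and standardize it", {
  segs <- make_segments(8, "N-FM", wl = 950, seed = 3)
  xb <- spectrogram_batch(segs)
  st <- fit_global_stats(xb)
  expect_gt(st$global_sd, 0)
  xb2 <- spectrogram_batch(segs, st)
  expect_equal(mean(xb2), 0, tolerance = 1e-9)
  expect_equal(sd(as.vector(xb2)), 1, tolerance = 1e-9)
  # applying the stats elsewhere does not change the fitted object
  before <- unclass(st)
  other <- make_segments(3, "N-FM", wl = 950, seed = 4)
  invisible(spectrogram_batch(other, st))
  expect_identical(unclass(st), before)
  # translation equivariance: shifting the data shifts the mean only
  st2 <- fit_global_stats(xb + 5)
  expect_equal(st2$global_mean, st$global_mean + 5, tolerance = 1e-9)
  expect_equal(st2$global_sd, st$global_sd, tolerance = 1e-9)
})

test_that("degenerate all-equal input cannot yield statistics", {
  expect_error(fit_global_stats(array(1, c(2, 3, 3))), "variance")
})

test_that("statistics survive a YAML round trip byte-for-byte in effect", {
  segs <- make_segments(2, "N-FM", wl = 950, seed = 5)
  xb <- spectrogram_batch(segs)
  st <- fit_global_stats(xb)
  p <- withr::local_tempfile(fileext = ".yml")
  write_norm_stats(st, p)
  st2 <- read_norm_stats(p)
  s1 <- transform_segment(segs$samples[1, , ], st)
  s2 <- transform_segment(segs$samples[1, , ], st2)
  expect_equal(s1$values, s2$values, tolerance = 1e-12)
})

test_that("identical segments produce identical spectrograms", {
  segs <- make_segments(1, "FM", wl = 950, seed = 6)
  a <- transform_segment(segs$samples[1, , ])
  b <- transform_segment(segs$samples[1, , ])
  expect_identical(a$values, b$values)
  expect_equal(dim(a$values), c(3, 129, 6))
})

test_that("segment transform agrees with the per-channel STFT", {
  segs <- make_segments(1, "N-FM", wl = 950, seed = 7)
  sp <- transform_segment(segs$samples[1, , ])
  merged <- merge_axes(segs$samples[1, , ])
  for (ch in 1:3)
    expect_equal(sp$values[ch, , ], unclass(stft_log(merged[, ch]))[, ],
                 tolerance = 1e-12, ignore_attr = TRUE)
})
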