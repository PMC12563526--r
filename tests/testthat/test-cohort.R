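test_that("configuration invariants are enforced", {
  expect_error(fm_cohort_config(fm_prevalence = 0.6), "fm_prevalence")
  expect_error(fm_cohort_config(fm_prevalence = 0), "fm_prevalence")
  expect_error(fm_cohort_config(noise_sd = -1), "noise_sd")
  expect_error(fm_cohort_config(fm_band_hz = c(20, 1)), "band")
  expect_error(fm_cohort_config(fm_burst_duration_s = c(2, 1)), "burst")
})

test_that("identical config and seed reproduce a recording exactly", {
  cfg <- fm_cohort_config(session_duration_s = 120)
  r1 <- generate_recording(cfg, "A", 4, seed = 11)
  r2 <- generate_recording(cfg, "A", 4, seed = 11)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$button_presses, r2$button_presses)
  expect_identical(r1$confirmed_intervals, r2$confirmed_intervals)
  r3 <- generate_recording(cfg, "A", 4, seed = 12)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("zero requested events gives an empty annotation stream", {
  r <- generate_recording(quiet_config(80), "A", 0, seed = 1)
  expect_equal(nrow(r$confirmed_intervals), 0)
  expect_length(r$button_presses, 0)
})

test_that("events that cannot fit raise a configuration error", {
  expect_error(generate_recording(quiet_config(30), "A", 10, seed = 1),
               "cannot place")
})

test_that("every dual-confirmed event is paired with a coincident press", {
  r <- generate_recording(fm_cohort_config(session_duration_s = 300), "A",
                          8, seed = 5)
  ci <- r$confirmed_intervals
  paired <- vapply(seq_len(nrow(ci)), function(i) {
    d <- pmax(0, pmax(ci[i, 1] - r$button_presses,
                      r$button_presses - ci[i, 2]))
    any(d <= 2.0)
  }, logical(1))
  expect_gte(sum(paired), 8)
})

test_that("band-limited burst energy dominates during events at high SNR", {
  cfg <- quiet_config(80, fm_snr_db = 20)
  r <- generate_recording(cfg, "A", 3, seed = 3)
  segs <- segment_and_label(r)
  e <- vapply(seq_len(length(segs)), function(i)
    band_energy(segs$samples[i, , ]), numeric(1))
  fm <- e[segs$label == "FM"]
  nfm <- e[segs$label == "N-FM"]
  expect_length(fm, 3)
  expect_gt(min(fm), max(nfm))
})

test_that("segment count depends only on duration, not content", {
  for (d in c(27, 60.2, 99.9)) {
    r <- generate_recording(quiet_config(d), "A", 1, seed = 2)
    expect_equal(length(segment_and_label(r)), floor(d / 5))
  }
})

test_that("a band-power threshold classifier separates classes at 6 dB", {
  segs <- cached("sep_segs", {
    cfg <- fm_cohort_config(n_subjects = 4,
                            session_duration_s = (130 + 0.5) * 5,
                            fm_snr_db = 6, fm_prevalence = 0.05)
    do.call(bind_segments,
            lapply(generate_cohort(cfg, seed = 21), segment_and_label))
  })
  expect_gte(length(segs), 500)
  e <- vapply(seq_len(length(segs)), function(i)
    band_energy(segs$samples[i, , ]), numeric(1))
  f1 <- vapply(sort(unique(e)), function(th)
    fm_metrics(confusion_counts(ifelse(e > th, "FM", "N-FM"),
                                segs$label))$F1, numeric(1))
  expect_gte(max(f1, na.rm = TRUE), 80)
})

test_that("recording CSV round trip is lossless to the written precision", {
  r <- generate_recording(fm_cohort_config(session_duration_s = 40), "A", 2,
                          seed = 9)
  p <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(r, p)
  r2 <- read_recording_csv(p, subject_id = "A")
  expect_equal(r2$sample_rate_hz, 190)
  expect_lt(max(abs(r$samples - r2$samples)), 1e-5)
  expect_equal(r$button_presses, r2$button_presses, tolerance = 1e-5)
  expect_equal(unname(r$confirmed_intervals), unname(r2$confirmed_intervals),
               tolerance = 1e-5)
})

test_that("empty events section reads back as a recording with no presses", {
  r <- generate_recording(quiet_config(40), "A", 0, seed = 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(r, p)
  r2 <- read_recording_csv(p)
  expect_length(r2$button_presses, 0)
  expect_equal(nrow(r2$confirmed_intervals), 0)
})

test_that("malformed CSV input raises parse errors naming the line", {
  r <- generate_recording(quiet_config(40), "A", 1, seed = 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(r, p)
  lines <- readLines(p)
  bad <- sub("^time_s", "seconds", lines)
  writeLines(bad, p)
  expect_error(read_recording_csv(p), "line 1")
  lines[5] <- sub(",[^,]*$", ",oops", lines[5])
  writeLines(lines, p)
  expect_error(read_recording_csv(p), "line 5")
})
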