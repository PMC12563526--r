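test_that("metrics follow the confusion-matrix formulas", {
  m <- fm_metrics(list(tp = 90, tn = 0, fp = 0, fn = 10))
  expect_equal(m$SEN, 90)
  expect_equal(m$PRE, 100)
  expect_equal(m$F1, 2 * 90 * 100 / 190)
  perfect <- fm_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(SEN = 100, PRE = 100, F1 = 100))
})

test_that("undefined ratios surface as NA, never as zero", {
  # no positive predictions: precision undefined
  m <- fm_metrics(list(tp = 0, tn = 10, fp = 0, fn = 2))
  expect_true(is.na(m$PRE))
  expect_equal(m$SEN, 0)
  expect_true(is.na(m$F1))
  # no positive truth: sensitivity undefined
  m2 <- fm_metrics(list(tp = 0, tn = 10, fp = 1, fn = 0))
  expect_true(is.na(m2$SEN))
})

test_that("metrics agree with a brute-force recount on random labels", {
  set.seed(1)
  for (rep in 1:25) {
    n <- sample(20:100, 1)
    truth <- sample(c("FM", "N-FM"), n, replace = TRUE)
    pred <- sample(c("FM", "N-FM"), n, replace = TRUE)
    cc <- confusion_counts(pred, truth)
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, n)
    m <- fm_metrics(cc)
    sen <- 100 * sum(pred == "FM" & truth == "FM") / sum(truth == "FM")
    expect_equal(m$SEN, sen)
    if (!is.na(m$F1)) {
      expect_gte(m$F1, min(m$SEN, m$PRE) - 1e-9)
      expect_lte(m$F1, max(m$SEN, m$PRE) + 1e-9)
    }
  }
})

test_that("the Pareto set matches exhaustive dominance checking", {
  one <- data.frame(model = "a", F1 = 90, params = 1e5, macs = 1e6)
  expect_true(tradeoff_report(one)$pareto)
  df <- data.frame(model = c("big", "mid", "bad"),
                   F1 = c(92, 90, 89),
                   params = c(2e6, 3e5, 4e5),
                   macs = c(5e7, 1e7, 2e7))
  out <- tradeoff_report(df)
  expect_equal(out$model, c("big", "mid", "bad")) # sorted by F1
  expect_equal(out$pareto[out$model == "bad"], FALSE) # dominated by mid
  expect_true(all(out$pareto[out$model %in% c("big", "mid")]))
  # brute-force oracle on random tables
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    d <- data.frame(model = paste0("m", 1:n), F1 = runif(n, 70, 95),
                    params = runif(n, 1e5, 1e6), macs = runif(n, 1e6, 1e8))
    out <- tradeoff_report(d)
    for (i in seq_len(n)) {
      mi <- out[out$model == d$model[i], ]
      dominated <- FALSE
      for (j in seq_len(n)) {
        if (i == j) next
        if (d$F1[j] >= d$F1[i] && d$params[j] <= d$params[i] &&
            d$macs[j] <= d$macs[i] &&
            (d$F1[j] > d$F1[i] || d$params[j] < d$params[i] ||
             d$macs[j] < d$macs[i]))
          dominated <- TRUE
      }
      expect_equal(mi$pareto, !dominated)
    }
  }
})

test_that("the distillation-grid report pivots and picks the best", {
  df <- expand.grid(student = c("S1", "S2"), teacher = "T1",
                    temperature = c(1, 3), alpha = c(0.3, 0.5))
  df$F1_mean <- 80
  df$F1_mean[df$student == "S1" & df$temperature == 3 & df$alpha == 0.5] <- 91
  # S2 ties everywhere: smaller temperature then smaller alpha wins
  rep <- kd_grid_report(df)
  expect_equal(nrow(rep$table), 8)
  b1 <- rep$best[rep$best$student == "S1", ]
  expect_equal(b1$F1_mean, 91)
  b2 <- rep$best[rep$best$student == "S2", ]
  expect_equal(b2$temperature, 1)
  expect_equal(b2$alpha, 0.3)
  single <- kd_grid_report(data.frame(temperature = 3, alpha = 0.5,
                                      F1_mean = 88))
  expect_equal(single$best$F1_mean, 88)
})

test_that("the ratio sweep balances classes and resumes from its manifest", {
  fm <- make_segments(6, "FM", wl = 950, seed = 1)
  nfm <- make_segments(30, "N-FM", wl = 950, seed = 2)
  val <- make_segments(8, c("FM", "N-FM"), wl = 950, seed = 3)
  p <- withr::local_tempfile(fileext = ".csv")
  out <- ratio_sweep(fm, nfm, val, factors = list(c(2, 12)),
                     model_specs = list(tiny = tiny_spec()), seeds = 1,
                     out_csv = p, max_epochs = 1, patience = 1,
                     batch_size = 12)
  expect_equal(nrow(out), 1)
  expect_equal(out$aug_factor, 2)
  expect_equal(out$under_target, 12)
  expect_true(file.exists(p))
  # resuming with the same manifest re-trains nothing and keeps one row
  t0 <- Sys.time()
  out2 <- ratio_sweep(fm, nfm, val, factors = list(c(2, 12)),
                      model_specs = list(tiny = tiny_spec()), seeds = 1,
                      out_csv = p, max_epochs = 1, patience = 1,
                      batch_size = 12)
  expect_equal(nrow(out2), 1)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
  # infeasible target is skipped with a message
  expect_message(
    out3 <- ratio_sweep(fm, nfm, val, factors = list(c(2, 1000)),
                        model_specs = list(tiny = tiny_spec()), seeds = 1,
                        max_epochs = 1, patience = 1, batch_size = 12),
    "infeasible")
  expect_null(out3)
})
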