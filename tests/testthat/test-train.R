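test_that("training learns linearly separable toy spectrograms", {
  x <- toy_spectro_data(48, seed = 1)
  xv <- toy_spectro_data(16, seed = 2)
  fit <- fm_train(tiny_spec(dropout = 0), x, x_val = xv,
                  lr = 1e-3, batch_size = 16, max_epochs = 20,
                  patience = 20, seed = 1)
  pred <- predict(fit, x)
  m <- fm_metrics(confusion_counts(pred, attr(x, "labels")))
  expect_gte(m$F1, 99.9)
  expect_s3_class(fit, "fm_fit")
  expect_true(all(c("epoch", "train_loss", "val_loss", "val_f1") %in%
                  names(fit$history)))
})

test_that("no teacher and alpha = 0 with a teacher coincide exactly", {
  x <- toy_spectro_data(32, seed = 3)
  xv <- toy_spectro_data(16, seed = 4)
  teacher_logits <- list(train = matrix(rnorm(64), 32, 2),
                         val = matrix(rnorm(32), 16, 2))
  f1 <- fm_train(tiny_spec(), x, x_val = xv, max_epochs = 3, patience = 5,
                 batch_size = 16, seed = 5)
  f2 <- fm_train(tiny_spec(), x, x_val = xv, max_epochs = 3, patience = 5,
                 batch_size = 16, seed = 5, teacher = teacher_logits,
                 alpha = 0, temperature = 3)
  expect_equal(f1$history$train_loss, f2$history$train_loss,
               tolerance = 1e-12)
  expect_equal(f1$history$val_loss, f2$history$val_loss, tolerance = 1e-12)
})

test_that("patience zero stops one epoch past the first non-improvement", {
  x <- toy_spectro_data(16, seed = 6)
  # zero learning rate: the validation loss can never improve after epoch 1
  fit <- fm_train(tiny_spec(dropout = 0), x, x_val = x, lr = 0,
                  batch_size = 16, max_epochs = 10, patience = 0, seed = 1)
  expect_equal(nrow(fit$history), 2)
  expect_equal(fit$best_epoch, 1)
})

test_that("best-validation-loss weights are restored", {
  x <- toy_spectro_data(32, seed = 7)
  xv <- toy_spectro_data(16, seed = 8)
  fit <- fm_train(tiny_spec(), x, x_val = xv, max_epochs = 6, patience = 6,
                  batch_size = 16, seed = 2)
  zl <- predict(fit, xv, type = "logits")
  l <- fmdetect:::kd_loss_batch(zl, NULL,
                                match(attr(xv, "labels"),
                                      c("FM", "N-FM")), 1, 0)$loss
  expect_equal(l, min(fit$history$val_loss), tolerance = 1e-9)
})

test_that("repeated training aggregates per-seed metrics", {
  x <- toy_spectro_data(32, seed = 9)
  xv <- toy_spectro_data(16, seed = 10)
  res <- fm_train_repeated(tiny_spec(), x, x_val = xv, seeds = 1:2,
                           max_epochs = 3, patience = 3, batch_size = 16)
  expect_equal(nrow(res$per_seed), 2)
  expect_true(all(res$per_seed$F1 >= 0 & res$per_seed$F1 <= 100, na.rm = TRUE))
  expect_gte(res$sd[["F1"]], 0)
  expect_equal(res$mean[["F1"]], mean(res$per_seed$F1), tolerance = 1e-12)
})

test_that("grid search enumerates the full Cartesian grid", {
  x <- toy_spectro_data(16, seed = 11)
  # one-point grid returns that configuration
  g1 <- grid_search(tiny_spec(), x, x_val = x,
                    grid = list(temperature = 3, alpha = 0.5,
                                batch_size = 16),
                    teacher = list(train = matrix(0, 16, 2),
                                   val = matrix(0, 16, 2)),
                    seeds = 1, max_epochs = 1, patience = 1)
  expect_equal(nrow(g1$results), 1)
  expect_equal(g1$best_config$temperature, 3)
  # 5 temperatures x 3 alphas = 15 rows, one per configuration
  g <- grid_search(tiny_spec(), x, x_val = x,
                   grid = list(temperature = c(1, 3, 5, 7, 9),
                               alpha = c(0.3, 0.5, 0.7), batch_size = 16),
                   teacher = list(train = matrix(0, 16, 2),
                                  val = matrix(0, 16, 2)),
                   seeds = 1, max_epochs = 1, patience = 1)
  expect_equal(nrow(g$results), 15)
  expect_equal(nrow(unique(g$results[, c("temperature", "alpha")])), 15)
  expect_error(grid_search(tiny_spec(), x, x_val = x,
                           grid = list(bogus = 1)), "unknown grid")
})

test_that("training diverging to non-finite loss aborts with a message", {
  x <- toy_spectro_data(16, seed = 12)
  m <- build_model(tiny_spec(), seed = 1)
  # a corrupted classifier bias makes every batch loss non-finite
  m$layers[[length(m$layers)]]$b[1] <- NaN
  expect_error(fm_train(m, x, x_val = x, batch_size = 16,
                        max_epochs = 5, patience = 5, seed = 1),
               "diverged")
})
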