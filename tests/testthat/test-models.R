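test_that("registered presets hit their parameter budgets", {
  s1 <- build_model("student_inverted_residual", seed = 1)
  s2 <- build_model("student_shuffle", seed = 1)
  s3 <- build_model("student_fire", seed = 1)
  tt <- build_model("teacher_large", seed = 1)
  expect_equal(round(s1$n_params / 1e6, 2), 0.32)
  expect_equal(round(s2$n_params / 1e6, 2), 0.31)
  expect_equal(round(s3$n_params / 1e6, 2), 0.27)
  expect_true(tt$n_params >= 1e6 && tt$n_params <= 5e6)
  # within 2% of the registered budgets
  expect_lt(abs(s1$n_params - 0.32e6) / 0.32e6, 0.02)
  expect_lt(abs(s2$n_params - 0.31e6) / 0.31e6, 0.02)
  expect_lt(abs(s3$n_params - 0.27e6) / 0.27e6, 0.02)
})

test_that("preset 1 parameter count matches an independent layer tally", {
  # hand accounting: conv = kh*kw*cin/g*cout + cout; block sums
  ir <- function(cin, cout, t = 4) {
    mid <- t * cin
    (cin * mid + mid) + (9 * mid + mid) + (mid * cout + cout)
  }
  tally <- (3 * 3 * 3 * 16 + 16) +
    ir(16, 24) + ir(24, 24) + ir(24, 40) + ir(40, 40) +
    ir(40, 80) + ir(80, 80) + ir(80, 112) + ir(112, 112) +
    (112 * 352 + 352) + (352 * 2 + 2)
  expect_equal(build_model("student_inverted_residual", 1)$n_params, tally)
  expect_equal(tally, 318050)
})

test_that("initialization is deterministic under the seed", {
  a <- build_model("student_fire", seed = 7)
  b <- build_model("student_fire", seed = 7)
  d <- build_model("student_fire", seed = 8)
  expect_identical(fmdetect:::nn_get_params(a$layers),
                   fmdetect:::nn_get_params(b$layers))
  expect_false(identical(fmdetect:::nn_get_params(a$layers),
                         fmdetect:::nn_get_params(d$layers)))
})

test_that("MAC accounting matches closed forms", {
  # single 1x1 convolution, 1 -> 1 channel on a 4x4 grid: 16 MACs
  l <- list(fmdetect:::layer_conv(1, 1, 1, 1))
  expect_equal(fmdetect:::shape_prop(l, c(4, 4, 1))$macs, 16)
  # doubling both channel counts of a pointwise layer quadruples MACs
  m1 <- fmdetect:::shape_prop(list(fmdetect:::layer_conv(1, 1, 8, 16)),
                              c(10, 5, 8))$macs
  m2 <- fmdetect:::shape_prop(list(fmdetect:::layer_conv(1, 1, 16, 32)),
                              c(10, 5, 16))$macs
  expect_equal(m2, 4 * m1)
  # dense layer: in x out
  expect_equal(fmdetect:::shape_prop(list(fmdetect:::layer_dense(20, 3)),
                                     20)$macs, 60)
})

test_that("preset 1 MACs match an independent spreadsheet-style tally", {
  # spatial schedule: 129x6 -> 65x6 -> 33x6 -> 17x6 -> 9x3 (frequency
  # stride 2 per stage; time stride 2 only in the fourth downsampling)
  conv <- function(k, cin, cout, h, w) k * k * cin * cout * h * w
  pw <- function(cin, cout, h, w) cin * cout * h * w
  dw <- function(c, h, w) 9 * c * h * w
  ir <- function(cin, cout, hin, win, hout, wout) {
    mid <- 4 * cin
    pw(cin, mid, hin, win) + dw(mid, hout, wout) + pw(mid, cout, hout, wout)
  }
  tally <- conv(3, 3, 16, 65, 6) +
    ir(16, 24, 65, 6, 33, 6) + ir(24, 24, 33, 6, 33, 6) +
    ir(24, 40, 33, 6, 17, 6) + ir(40, 40, 17, 6, 17, 6) +
    ir(40, 80, 17, 6, 9, 3) + ir(80, 80, 9, 3, 9, 3) +
    ir(80, 112, 9, 3, 9, 3) + ir(112, 112, 9, 3, 9, 3) +
    pw(112, 352, 9, 3) + 352 * 2
  expect_equal(count_flops(build_model("student_inverted_residual", 1)),
               tally)
})

test_that("incompatible input shape raises a build error", {
  spec <- fm_model_spec("student_inverted_residual",
                        input_shape = c(129L, 6L, 4L))
  expect_error(build_model(spec), "incompatible")
})

test_that("width multiplier scales parameters and stays buildable", {
  small <- build_model(fm_model_spec("student_inverted_residual",
                                     width_multiplier = 0.5), seed = 1)
  expect_lt(small$n_params, 318050 / 2)
  p <- predict(small, array(rnorm(2 * 129 * 6 * 3), c(2, 129, 6, 3)),
               type = "prob")
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-9)
})

test_that("temperature softmax behaves as stated", {
  expect_equal(softmax_T(c(0, 0), 5), c(0.5, 0.5))
  z <- c(2, -1, 0.5)
  # T = 1 equals the direct exp-normalize computation
  expect_equal(softmax_T(z, 1), exp(z) / sum(exp(z)), tolerance = 1e-12)
  expect_equal(sum(softmax_T(z, 3)), 1)
  # entropy grows monotonically with temperature
  ent <- function(p) -sum(p * log(p))
  es <- vapply(c(0.5, 1, 3, 9, 27), function(T) ent(softmax_T(z, T)),
               numeric(1))
  expect_true(all(diff(es) > 0))
  expect_error(softmax_T(z, 0), "temperature")
})

test_that("the distillation loss reduces and zeroes as the formula says", {
  zs <- c(1.2, -0.3)
  zt <- c(2.0, 0.1)
  # alpha = 0 is plain cross-entropy
  ce <- -log(softmax_T(zs, 1)[1])
  expect_equal(kd_loss(zs, zt, 1, T = 5, alpha = 0), ce, tolerance = 1e-12)
  # identical logits zero the KL term for any temperature
  for (T in c(1, 3, 9))
    expect_equal(kd_loss(zs, zs, 1, T = T, alpha = 0.5), 0.5 * ce,
                 tolerance = 1e-12)
  # hand-computed value for zs=(1,0), zt=(2,0), y=1, T=2, alpha=0.5:
  # CE = -log(e/(e+1)); KL(p||q) with p=softmax(1,0), q=softmax(0.5,0)
  p <- exp(c(1, 0)) / sum(exp(c(1, 0)))
  q <- exp(c(0.5, 0)) / sum(exp(c(0.5, 0)))
  manual <- 0.5 * (-log(p[1])) + 0.5 * 4 * sum(p * log(p / q))
  expect_equal(kd_loss(c(1, 0), c(2, 0), 1, T = 2, alpha = 0.5), manual,
               tolerance = 1e-12)
  # non-negative and continuous over random draws
  set.seed(3)
  for (rep in 1:50) {
    zs <- rnorm(2); zt <- rnorm(2)
    a <- runif(1); T <- runif(1, 0.5, 9)
    expect_gte(kd_loss(zs, zt, sample(1:2, 1), T, a), 0)
  }
})

test_that("the analytic gradient passes central finite differences", {
  set.seed(4)
  for (rep in 1:20) {
    zs <- rnorm(2); zt <- rnorm(2)
    y <- sample(1:2, 1); T <- runif(1, 0.5, 9); a <- runif(1)
    g <- kd_loss_grad(zs, zt, y, T, a)
    num <- vapply(1:2, function(i) {
      e <- 1e-6
      zp <- zs; zp[i] <- zp[i] + e
      zm <- zs; zm[i] <- zm[i] - e
      (kd_loss(zp, zt, y, T, a) - kd_loss(zm, zt, y, T, a)) / (2 * e)
    }, numeric(1))
    expect_equal(g, num, tolerance = 1e-5)
  }
})
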