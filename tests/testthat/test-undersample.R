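test_that("composite distance follows the stated formula", {
  expect_equal(composite_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  # hand arithmetic: 0.7 * (2/2) + 0.3 * (1 - 0) = 1.0
  expect_equal(composite_distance(c(1, 0), c(0, 1)), 1.0)
  set.seed(1)
  for (rep in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(composite_distance(a, b), composite_distance(b, a))
    expect_gte(composite_distance(a, b), 0)
  }
  # zero-vector cosine is defined as zero similarity
  expect_equal(composite_distance(c(0, 0), c(1, 1)),
               0.7 * 2 / 2 + 0.3 * 1)
  expect_error(composite_distance(1:3, 1:4), "dimension")
  expect_error(composite_distance(1:3, 4:6, 0.5, 0.4), "sum to 1")
})

test_that("the C++ distance kernel agrees with the scalar definition", {
  set.seed(2)
  X <- matrix(rnorm(40), 8, 5)
  C <- matrix(rnorm(15), 3, 5)
  D <- fmdetect:::composite_dist_t_cpp(t(X), t(C), 0.7, 0.3)
  for (i in 1:8) for (j in 1:3)
    expect_equal(D[i, j], composite_distance(X[i, ], C[j, ]),
                 tolerance = 1e-12)
})

test_that("k = 1 reduces to the coordinate-wise mean", {
  set.seed(3)
  X <- matrix(rnorm(200), 40, 5)
  km <- kmeans_fit(X, k = 1, seed = 1)
  expect_equal(as.vector(km$centroids), colMeans(X), tolerance = 1e-9)
  expect_equal(km$wcss, sum(sweep(X, 2, colMeans(X))^2), tolerance = 1e-9)
})

test_that("well-separated blobs are recovered exactly", {
  set.seed(4)
  X <- rbind(matrix(rnorm(100, mean = 8), 20, 5),
             matrix(rnorm(100, mean = -8), 20, 5))
  truth <- rep(1:2, each = 20)
  km <- kmeans_fit(X, k = 2, seed = 2)
  expect_equal(length(unique(km$assignments[1:20])), 1)
  expect_equal(length(unique(km$assignments[21:40])), 1)
  expect_false(km$assignments[1] == km$assignments[21])
  # nearest-centroid brute force agrees with the stored assignment
  D <- fmdetect:::composite_dist_t_cpp(t(X), t(km$centroids), 0.7, 0.3)
  expect_equal(km$assignments, max.col(-D, ties.method = "first"))
})

test_that("the squared-Euclidean iteration descends the WCSS objective", {
  set.seed(5)
  for (rep in 1:25) {
    X <- matrix(rnorm(sample(50:150, 1) * 6), ncol = 6)
    km <- kmeans_fit(X, k = 4, seed = rep, metric = "euclidean")
    expect_true(all(diff(km$wcss_trace) <= 1e-8 * km$wcss_trace[1]))
    expect_lte(km$iterations_run, 300)
  }
})

test_that("clustering is deterministic under a fixed seed", {
  set.seed(6)
  X <- matrix(rnorm(600), 100, 6)
  k1 <- kmeans_fit(X, 5, seed = 9)
  k2 <- kmeans_fit(X, 5, seed = 9)
  expect_identical(k1$assignments, k2$assignments)
  expect_identical(k1$centroids, k2$centroids)
})

test_that("largest-remainder quotas match hand arithmetic", {
  expect_equal(fmdetect:::apportion_quota(c(60, 40), 10), c(6L, 4L))
  expect_equal(fmdetect:::apportion_quota(c(5, 5, 5), 15), c(5L, 5L, 5L))
  q <- fmdetect:::apportion_quota(c(7, 3, 11), 10)
  expect_equal(sum(q), 10)
  expect_true(all(q <= c(7, 3, 11)))
})

test_that("stratified selection returns distinct in-range indices", {
  set.seed(7)
  X <- matrix(rnorm(80 * 6), 80, 6)
  km <- kmeans_fit(X, 4, seed = 1)
  expect_equal(stratified_select(km, X, 80), 1:80)
  idx <- stratified_select(km, X, 25)
  expect_length(idx, 25)
  expect_false(anyDuplicated(idx) > 0)
  expect_true(all(idx >= 1 & idx <= 80))
  # per-cluster counts follow the quota
  quota <- fmdetect:::apportion_quota(km$sizes, 25)
  got <- tabulate(km$assignments[idx], km$k)
  expect_equal(got, quota)
  expect_identical(idx, stratified_select(km, X, 25))
})

test_that("undersampling returns an exact duplicate-free subset", {
  segs <- make_segments(40, "N-FM", wl = 950, seed = 8)
  out <- undersample_majority(segs, 15, k = 4, seed = 1)
  expect_length(out, 15)
  expect_true(all(out$label == "N-FM"))
  # every retained segment matches a distinct input row
  key <- apply(segs$samples[, 1:5, 1, drop = FALSE], 1, paste, collapse = ",")
  okey <- apply(out$samples[, 1:5, 1, drop = FALSE], 1, paste, collapse = ",")
  expect_true(all(okey %in% key))
  expect_false(anyDuplicated(okey) > 0)
  # n_target = n is the identity (set-wise)
  all40 <- undersample_majority(segs, 40, k = 4, seed = 1)
  expect_equal(sort(apply(all40$samples[, 1:5, 1, drop = FALSE], 1, paste,
                          collapse = ",")), sort(key))
})

test_that("augmentation plus undersampling balances the classes", {
  fm <- make_segments(6, "FM", wl = 950, seed = 9)
  nfm <- make_segments(31, "N-FM", wl = 950, seed = 10)
  f <- 3
  aug <- augment_minority(fm, f, seed = 1)
  sel <- undersample_majority(nfm, length(aug), k = 3, seed = 1)
  expect_equal(length(aug), length(sel))
  expect_equal(length(aug), f * length(fm))
})

test_that("silhouette search picks a plausible k on separated blobs", {
  set.seed(11)
  X <- do.call(rbind, lapply(c(-12, 0, 12), function(m)
    matrix(rnorm(40 * 4, mean = m), 40, 4)))
  k <- fmdetect:::choose_k_silhouette(X, k_range = 2:6, seed = 1)
  expect_equal(k, 3)
})
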