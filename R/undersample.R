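#' Composite Manhattan/cosine distance
#'
#' Weighted combination of a dimensionality-normalized Manhattan (L1)
#' distance and a cosine dissimilarity:
#' `w_manhattan * L1(a, b) / d + w_cosine * (1 - cos_sim(a, b))`,
#' where `d` is the feature dimensionality. The L1 term is normalized by
#' `d` so the two components share scale. The cosine similarity involving
#' a zero vector is defined as 0 (distance contribution 1).
#'
#' @param a,b numeric feature vectors of equal length.
#' @param w_manhattan,w_cosine non-negative weights summing to 1.
#' @return non-negative scalar distance.
#' @export
composite_distance <- function(a, b, w_manhattan = 0.7, w_cosine = 0.3) {
  if (length(a) != length(b))
    stop("composite_distance: dimension mismatch", call. = FALSE)
  if (abs(w_manhattan + w_cosine - 1) > 1e-12)
    stop("weights must sum to 1", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  cs <- if (na > 0 && nb > 0) sum(a * b) / (na * nb) else 0
  w_manhattan * sum(abs(a - b)) / length(a) + w_cosine * (1 - cs)
}

#' Adaptive k-means with a composite assignment metric
#'
#' Lloyd-style iteration tailored to majority-class undersampling: samples
#' are assigned to the nearest centroid, centroids are updated as
#' coordinate-wise means, and the within-cluster sum of squared errors
#' (WCSS, squared Euclidean) is recorded after every update. Iteration
#' stops when the largest centroid shift falls below `tol`, when
#' assignments stop changing, or at `max_iter`. An emptied cluster is
#' re-seeded at the sample farthest from its current centroid.
#'
#' Two assignment metrics are available. `"composite"` (the default) uses
#' the weighted Manhattan/cosine metric of [composite_distance()]; note
#' that under this assignment the mean update no longer guarantees a
#' monotone WCSS trace, since the WCSS objective is squared-Euclidean.
#' `"euclidean"` is the classical iteration that exactly minimizes the
#' WCSS objective, for which the per-iteration descent property holds.
#'
#' @param X numeric matrix, samples in rows.
#' @param k number of clusters (the default 12 matches the pipeline's
#'   registered setting); if `adaptive = TRUE`, `k` is instead chosen from
#'   `k_range` by mean silhouette on a subsample.
#' @param max_iter maximum Lloyd iterations.
#' @param tol convergence tolerance on the largest centroid shift
#'   (Euclidean norm).
#' @param seed seed for centroid initialization.
#' @param w_manhattan,w_cosine composite metric weights.
#' @param metric assignment metric, `"composite"` or `"euclidean"`.
#' @param adaptive estimate k by silhouette search instead of using `k`.
#' @param k_range candidate k values for the adaptive search.
#' @return an object of class `fm_kmeans`: list with `k`, `centroids`
#'   (k x d), `assignments` (1-based), `wcss` (final value), `wcss_trace`
#'   (per iteration), `iterations_run`, `sizes`.
#' @export
kmeans_fit <- function(X, k = 12L, max_iter = 300L, tol = 1e-4, seed = 1L,
                       w_manhattan = 0.7, w_cosine = 0.3,
                       metric = c("composite", "euclidean"),
                       adaptive = FALSE, k_range = 4:24) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (adaptive)
    k <- choose_k_silhouette(X, k_range, seed = seed,
                             w_manhattan = w_manhattan, w_cosine = w_cosine)
  k <- as.integer(k)
  n <- nrow(X)
  if (n < k) stop("need at least k samples", call. = FALSE)
  C <- with_seed(seed, X[sample.int(n, k), , drop = FALSE])
  Xt <- t(X) # column-contiguous layout for the distance kernels
  assign_old <- rep(0L, n)
  trace <- numeric(0)
  iter <- 0L
  x_sq <- rowSums(X^2)
  repeat {
    iter <- iter + 1L
    D <- if (metric == "composite")
      composite_dist_t_cpp(Xt, t(C), w_manhattan, w_cosine)
    else # squared Euclidean, expanded form (argmin-equivalent)
      x_sq - 2 * tcrossprod(X, C) + rep(rowSums(C^2), each = nrow(X))
    assign <- max.col(-D, ties.method = "first")
    # re-seed empty clusters at the farthest-from-centroid sample
    for (j in which(tabulate(assign, k) == 0L)) {
      far <- which.max(D[cbind(seq_len(n), assign)])
      C[j, ] <- X[far, ]
      assign[far] <- j
    }
    Cnew <- t(cluster_sums_t_cpp(Xt, assign, k)) /
      as.vector(tabulate(assign, k))
    shift <- sqrt(max(rowSums((Cnew - C)^2)))
    C <- Cnew
    trace <- c(trace, wcss_t_cpp(Xt, t(C), assign))
    if (identical(assign, assign_old) || shift < tol || iter >= max_iter)
      break
    assign_old <- assign
  }
  structure(list(k = k, centroids = C, assignments = assign,
                 wcss = trace[length(trace)], wcss_trace = trace,
                 iterations_run = iter, sizes = tabulate(assign, k),
                 metric = metric,
                 w_manhattan = w_manhattan, w_cosine = w_cosine),
            class = "fm_kmeans")
}

#' @export
print.fm_kmeans <- function(x, ...) {
  cat(sprintf("<fm_kmeans> k = %d, %d iterations, WCSS = %.4g, sizes: %s\n",
              x$k, x$iterations_run, x$wcss,
              paste(x$sizes, collapse = " ")))
  invisible(x)
}

# mean-silhouette k search on a subsample under the composite metric
choose_k_silhouette <- function(X, k_range = 4:24, seed = 1L,
                                w_manhattan = 0.7, w_cosine = 0.3,
                                subsample = 500L) {
  n <- nrow(X)
  idx <- with_seed(seed, sample.int(n, min(n, subsample)))
  Xs <- X[idx, , drop = FALSE]
  best_k <- k_range[1]
  best_s <- -Inf
  for (k in k_range) {
    if (nrow(Xs) <= k) break
    km <- kmeans_fit(Xs, k, max_iter = 50L, seed = seed,
                     w_manhattan = w_manhattan, w_cosine = w_cosine)
    D <- composite_dist_t_cpp(t(Xs), t(km$centroids), w_manhattan, w_cosine)
    a <- D[cbind(seq_len(nrow(Xs)), km$assignments)]
    D[cbind(seq_len(nrow(Xs)), km$assignments)] <- Inf
    b <- apply(D, 1, min)
    s <- mean((b - a) / pmax(a, b))
    if (is.finite(s) && s > best_s) { best_s <- s; best_k <- k }
  }
  best_k
}

# largest-remainder apportionment of n_target by cluster size, capped at
# cluster capacity with overflow redistributed by remainder order
apportion_quota <- function(sizes, n_target) {
  k <- length(sizes)
  n <- sum(sizes)
  stopifnot(n_target <= n)
  exact <- n_target * sizes / n
  quota <- floor(exact)
  rem <- exact - quota
  left <- n_target - sum(quota)
  ord <- order(rem, sizes, decreasing = TRUE)
  i <- 1L
  while (left > 0L) {
    j <- ord[(i - 1L) %% k + 1L]
    if (quota[j] < sizes[j]) { quota[j] <- quota[j] + 1L; left <- left - 1L }
    i <- i + 1L
  }
  # cap any quota that exceeded capacity (possible only through rounding ties)
  over <- pmax(quota - sizes, 0)
  if (any(over > 0)) {
    quota <- pmin(quota, sizes)
    left <- n_target - sum(quota)
    for (j in ord) {
      if (left == 0L) break
      room <- sizes[j] - quota[j]
      add <- min(room, left)
      quota[j] <- quota[j] + add
      left <- left - add
    }
  }
  as.integer(quota)
}

#' Stratified dual-criterion selection from a clustering
#'
#' Per-cluster quotas are the largest-remainder apportionment of `n_target`
#' by cluster size. Inside each cluster picks alternate between a
#' centrality criterion (unpicked sample with the smallest Manhattan
#' distance to the centroid) and a diversity criterion (unpicked sample
#' minimizing the maximum cosine similarity to the already-picked samples
#' of that cluster), so the selection is both centrally representative and
#' diverse.
#'
#' @param model an `fm_kmeans` fit.
#' @param X the feature matrix the model was fitted on.
#' @param n_target total number of samples to select (`<= nrow(X)`).
#' @return integer vector of `n_target` distinct row indices into `X`.
#' @export
stratified_select <- function(model, X, n_target) {
  stopifnot(inherits(model, "fm_kmeans"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_target > n) stop("n_target exceeds sample count", call. = FALSE)
  if (n_target == n) return(seq_len(n))
  quota <- apportion_quota(model$sizes, n_target)
  Xt <- t(X)
  picked_all <- integer(0)
  for (j in seq_len(model$k)) {
    if (quota[j] == 0L) next
    idx <- which(model$assignments == j)
    sel <- select_cluster_cpp(Xt[, idx, drop = FALSE],
                              model$centroids[j, ], quota[j])
    picked_all <- c(picked_all, idx[sel])
  }
  sort(picked_all)
}

#' Undersample the majority class to a target count
#'
#' Clusters the majority segments in the feature space of their flattened
#' 3-channel log-spectrograms (globally standardized), then applies
#' [stratified_select()] to retain `n_target` representative, diverse
#' segments. Returns a subset of the input (no duplicates, labels and
#' samples untouched).
#'
#' @param majority an `fm_segments` object (typically all N-FM training
#'   segments), or `NULL` if `features` is given.
#' @param n_target number of segments to retain.
#' @param k,max_iter,tol,seed,w_manhattan,w_cosine,adaptive clustering
#'   parameters, see [kmeans_fit()].
#' @param features optional precomputed feature matrix (one row per
#'   segment) to cluster instead of computing spectrogram features.
#' @return if `majority` is given, an `fm_segments` subset of length
#'   `n_target`; otherwise the integer indices of the retained rows.
#' @export
undersample_majority <- function(majority, n_target, k = 12L,
                                 max_iter = 300L, tol = 1e-4, seed = 1L,
                                 w_manhattan = 0.7, w_cosine = 0.3,
                                 adaptive = FALSE, features = NULL) {
  if (is.null(features)) {
    stopifnot(inherits(majority, "fm_segments"))
    features <- segment_features(majority,
                                 attr(majority, "sample_rate_hz"))
  }
  n <- nrow(features)
  if (n_target > n) stop("n_target exceeds majority count", call. = FALSE)
  if (n_target == n) {
    idx <- seq_len(n)
  } else {
    km <- kmeans_fit(features, k = k, max_iter = max_iter, tol = tol,
                     seed = seed, w_manhattan = w_manhattan,
                     w_cosine = w_cosine, adaptive = adaptive)
    idx <- stratified_select(km, features, n_target)
  }
  if (is.null(majority)) idx else majority[idx]
}

# flattened, globally standardized log-spectrogram features used as the
# clustering space (matches the downstream model representation)
segment_features <- function(segments, sample_rate_hz = 190) {
  n <- length(segments)
  first <- transform_segment(segments$samples[1, , ],
                             sample_rate_hz = sample_rate_hz)
  d <- length(first$values)
  out <- matrix(0, n, d)
  out[1, ] <- as.vector(first$values)
  if (n > 1) for (i in 2:n)
    out[i, ] <- as.vector(transform_segment(segments$samples[i, , ],
                                            sample_rate_hz = sample_rate_hz)$values)
  mu <- mean(out)
  s <- stats::sd(out)
  if (s > 0) (out - mu) / s else out
}
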