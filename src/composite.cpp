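#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// pairwise Manhattan distances between columns of Xt (d x n) and columns
// of Ct (d x k); unrolled accumulators let the compiler vectorize the
// reduction without fast-math
static inline double l1_cols(const double* x, const double* c, uword d) {
  double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
  uword t = 0;
  for (; t + 4 <= d; t += 4) {
    a0 += std::abs(x[t] - c[t]);
    a1 += std::abs(x[t + 1] - c[t + 1]);
    a2 += std::abs(x[t + 2] - c[t + 2]);
    a3 += std::abs(x[t + 3] - c[t + 3]);
  }
  double l1 = (a0 + a1) + (a2 + a3);
  for (; t < d; ++t) l1 += std::abs(x[t] - c[t]);
  return l1;
}

// [[Rcpp::export]]
arma::mat l1_dist_t_cpp(const arma::mat& Xt, const arma::mat& Ct) {
  const uword d = Xt.n_rows, n = Xt.n_cols, k = Ct.n_cols;
  mat D(n, k);
  for (uword i = 0; i < n; ++i) {
    const double* x = Xt.colptr(i);
    for (uword j = 0; j < k; ++j)
      D(i, j) = l1_cols(x, Ct.colptr(j), d);
  }
  return D;
}

// Composite distance of every sample to every centre:
//   w_man * L1(x, c) / d  +  w_cos * (1 - cos_sim(x, c)),
// with the cosine similarity of/with a zero vector defined as 0.
// Samples and centres are passed TRANSPOSED (d x n and d x k).
// [[Rcpp::export]]
arma::mat composite_dist_t_cpp(const arma::mat& Xt, const arma::mat& Ct,
                               double w_man, double w_cos) {
  const uword d = Xt.n_rows, n = Xt.n_cols, k = Ct.n_cols;
  vec cn(k);
  for (uword j = 0; j < k; ++j) cn(j) = norm(Ct.col(j), 2);
  mat DP = Xt.t() * Ct; // BLAS
  mat D(n, k);
  for (uword i = 0; i < n; ++i) {
    const double* x = Xt.colptr(i);
    double xn = 0.0;
    for (uword t = 0; t < d; ++t) xn += x[t] * x[t];
    xn = std::sqrt(xn);
    for (uword j = 0; j < k; ++j) {
      const double l1 = l1_cols(x, Ct.colptr(j), d);
      const double denom = xn * cn(j);
      const double cs = denom > 0.0 ? DP(i, j) / denom : 0.0;
      D(i, j) = w_man * l1 / (double)d + w_cos * (1.0 - cs);
    }
  }
  return D;
}

// Within-cluster sum of squared (Euclidean) errors for a 1-based
// assignment; Xt is d x n, Ct is d x k.
// [[Rcpp::export]]
double wcss_t_cpp(const arma::mat& Xt, const arma::mat& Ct,
                  const arma::uvec& assign) {
  const uword d = Xt.n_rows, n = Xt.n_cols;
  double s = 0.0;
  for (uword i = 0; i < n; ++i) {
    const double* x = Xt.colptr(i);
    const double* c = Ct.colptr(assign(i) - 1);
    double acc = 0.0;
    for (uword t = 0; t < d; ++t) {
      const double diff = x[t] - c[t];
      acc += diff * diff;
    }
    s += acc;
  }
  return s;
}

// Per-cluster coordinate sums for the centroid update: one pass over the
// column-contiguous sample matrix. Returns d x k.
// [[Rcpp::export]]
arma::mat cluster_sums_t_cpp(const arma::mat& Xt, const arma::uvec& assign,
                             int k) {
  const uword d = Xt.n_rows, n = Xt.n_cols;
  mat S(d, (uword)k, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    double* s = S.colptr(assign(i) - 1);
    const double* x = Xt.colptr(i);
    for (uword t = 0; t < d; ++t) s[t] += x[t];
  }
  return S;
}

// Dual-criterion selection inside one cluster. Columns of Xct are the
// cluster's samples (d x m). Picks alternate between (i) the unpicked
// sample with the smallest Manhattan distance to the centroid and
// (ii) the unpicked sample minimizing the maximum cosine similarity to
// the already-picked set. Similarity updates run in single precision
// (one matrix-vector product per pick); ties break toward the smaller
// index. Returns 1-based local indices in pick order.
// [[Rcpp::export]]
arma::uvec select_cluster_cpp(const arma::mat& Xct, const arma::vec& centre,
                              int quota) {
  const uword d = Xct.n_rows, m = Xct.n_cols;
  fmat Xf = conv_to<fmat>::from(Xct);
  fvec norms(m);
  for (uword i = 0; i < m; ++i) norms(i) = norm(Xf.col(i), 2);
  // centrality order: Manhattan distance to the centroid, index tiebreak
  vec l1(m);
  for (uword i = 0; i < m; ++i) {
    const double* x = Xct.colptr(i);
    double acc = 0.0;
    for (uword t = 0; t < d; ++t) acc += std::abs(x[t] - centre(t));
    l1(i) = acc;
  }
  uvec ord = stable_sort_index(l1, "ascend");
  std::vector<bool> picked(m, false);
  fvec maxsim(m);
  maxsim.fill(-std::numeric_limits<float>::infinity());
  uvec sel((uword)quota);
  uword ci = 0;
  for (int t = 0; t < quota; ++t) {
    uword p;
    if (t % 2 == 0) { // centrality pick
      while (picked[ord(ci)]) ++ci;
      p = ord(ci);
    } else {          // diversity pick
      float best = std::numeric_limits<float>::infinity();
      p = 0;
      for (uword i = 0; i < m; ++i)
        if (!picked[i] && maxsim(i) < best) { best = maxsim(i); p = i; }
    }
    picked[p] = true;
    sel((uword)t) = p + 1;
    if (t + 1 < quota) {
      const float np = norms(p);
      if (np > 0.0f) {
        fvec cs = Xf.t() * Xf.col(p); // sgemv
        for (uword i = 0; i < m; ++i) {
          const float denom = norms(i) * np;
          const float v = denom > 0.0f ? cs(i) / denom : 0.0f;
          if (v > maxsim(i)) maxsim(i) = v;
        }
      } else {
        for (uword i = 0; i < m; ++i)
          if (maxsim(i) < 0.0f) maxsim(i) = 0.0f;
      }
    }
  }
  return sel;
}

// Manhattan distance of every column of Xt (d x n) to a single centre.
// [[Rcpp::export]]
arma::vec manhattan_to_t_cpp(const arma::mat& Xt, const arma::vec& c) {
  const uword d = Xt.n_rows, n = Xt.n_cols;
  vec out(n);
  for (uword i = 0; i < n; ++i) {
    const double* x = Xt.colptr(i);
    double l1 = 0.0;
    for (uword t = 0; t < d; ++t) l1 += std::abs(x[t] - c(t));
    out(i) = l1;
  }
  return out;
}
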