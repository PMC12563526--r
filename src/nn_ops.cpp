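#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// BLAS-backed helpers for the network engine. R arrays in NHWC layout are
// aliased as (N*H*W) x C matrices without copying (column-major layout
// makes the channel dimension the matrix column).

static arma::mat alias_mat(NumericVector& x, arma::uword nr, arma::uword nc) {
  return arma::mat(x.begin(), nr, nc, false, true);
}

// Convolution matrix products run in single precision (the standard
// working precision for CNN training): operands are converted to float,
// multiplied with sgemm, and the result widened back to double.
static arma::mat gemm32(const arma::mat& A, const arma::mat& B) {
  arma::fmat Af = arma::conv_to<arma::fmat>::from(A);
  arma::fmat Bf = arma::conv_to<arma::fmat>::from(B);
  return arma::conv_to<arma::mat>::from(Af * Bf);
}

static arma::mat gemm32_tn(const arma::mat& A, const arma::mat& B) {
  arma::fmat Af = arma::conv_to<arma::fmat>::from(A);
  arma::fmat Bf = arma::conv_to<arma::fmat>::from(B);
  return arma::conv_to<arma::mat>::from(Af.t() * Bf);
}

static arma::mat gemm32_nt(const arma::mat& A, const arma::mat& B) {
  arma::fmat Af = arma::conv_to<arma::fmat>::from(A);
  arma::fmat Bf = arma::conv_to<arma::fmat>::from(B);
  return arma::conv_to<arma::mat>::from(Af * Bf.t());
}

// pointwise (1x1, stride 1) convolution, optionally grouped
// [[Rcpp::export]]
NumericVector pw_fwd(NumericVector x, const arma::mat& w,
                     const arma::vec& b, int groups) {
  IntegerVector dm = x.attr("dim");
  const arma::uword rows = (arma::uword)dm[0] * dm[1] * dm[2];
  const arma::uword cin = dm[3], cout = w.n_cols;
  arma::mat X = alias_mat(x, rows, cin);
  NumericVector out(rows * cout);
  out.attr("dim") = IntegerVector::create(dm[0], dm[1], dm[2], (int)cout);
  arma::mat O(out.begin(), rows, cout, false, true);
  if (groups == 1) {
    O = gemm32(X, w);
  } else {
    const arma::uword cig = cin / groups, cog = cout / groups;
    for (int g = 0; g < groups; ++g)
      O.cols(g * cog, (g + 1) * cog - 1) =
        gemm32(X.cols(g * cig, (g + 1) * cig - 1),
               w.cols(g * cog, (g + 1) * cog - 1));
  }
  O.each_row() += b.t();
  return out;
}

// [[Rcpp::export]]
List pw_bwd(NumericVector x, const arma::mat& w, NumericVector dout,
            int groups) {
  IntegerVector dm = x.attr("dim");
  const arma::uword rows = (arma::uword)dm[0] * dm[1] * dm[2];
  const arma::uword cin = dm[3], cout = w.n_cols;
  arma::mat X = alias_mat(x, rows, cin);
  arma::mat G = alias_mat(dout, rows, cout);
  arma::mat dw(w.n_rows, cout);
  NumericVector dx(rows * cin);
  dx.attr("dim") = x.attr("dim");
  arma::mat DX(dx.begin(), rows, cin, false, true);
  if (groups == 1) {
    dw = gemm32_tn(X, G);
    DX = gemm32_nt(G, w);
  } else {
    const arma::uword cig = cin / groups, cog = cout / groups;
    for (int g = 0; g < groups; ++g) {
      dw.cols(g * cog, (g + 1) * cog - 1) =
        gemm32_tn(X.cols(g * cig, (g + 1) * cig - 1),
                  G.cols(g * cog, (g + 1) * cog - 1));
      DX.cols(g * cig, (g + 1) * cig - 1) =
        gemm32_nt(G.cols(g * cog, (g + 1) * cog - 1),
                  w.cols(g * cog, (g + 1) * cog - 1));
    }
  }
  arma::vec db = arma::sum(G, 0).t();
  return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx);
}

// GEMM + bias for im2col-style convolution
// [[Rcpp::export]]
NumericVector conv_mm_fwd(const arma::mat& col, const arma::mat& w,
                          const arma::vec& b, int N, int Hout, int Wout) {
  NumericVector out((R_xlen_t)col.n_rows * w.n_cols);
  out.attr("dim") = IntegerVector::create(N, Hout, Wout, (int)w.n_cols);
  arma::mat O(out.begin(), col.n_rows, w.n_cols, false, true);
  O = gemm32(col, w);
  O.each_row() += b.t();
  return out;
}

// [[Rcpp::export]]
List conv_mm_bwd(const arma::mat& col, const arma::mat& w,
                 NumericVector dout) {
  const arma::uword rows = col.n_rows, cout = w.n_cols;
  arma::mat G(dout.begin(), rows, cout, false, true);
  arma::mat dw = gemm32_tn(col, G);
  arma::vec db = arma::sum(G, 0).t();
  arma::mat dcol = gemm32_nt(G, w);
  return List::create(_["dw"] = dw, _["db"] = db, _["dcol"] = dcol);
}

// In-place rectifier. The engine only ever applies ReLU to freshly
// allocated intermediate tensors (layer outputs that no cache references),
// so mutating the buffer is safe and avoids a full copy + GC churn.
// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  double* p = x.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) p[i] = p[i] > 0 ? p[i] : 0;
  return x;
}

// mask recovered from the forward output (out > 0 iff input > 0);
// mutates the incoming gradient, which is likewise a fresh intermediate
// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector dout, NumericVector out) {
  const double* o = out.begin();
  double* p = dout.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) p[i] = o[i] > 0 ? p[i] : 0;
  return dout;
}

// global average pool over the spatial grid
// [[Rcpp::export]]
NumericMatrix gap_fwd(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  const int N = dm[0], P = dm[1] * dm[2], C = dm[3];
  NumericMatrix out(N, C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int p = 0; p < P; ++p) {
      const double* src = xp + (R_xlen_t)N * (p + (R_xlen_t)P * c);
      for (int n = 0; n < N; ++n) out(n, c) += src[n];
    }
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) out(n, c) /= P;
  return out;
}

// [[Rcpp::export]]
NumericVector gap_bwd(const NumericMatrix& dout, int H, int W) {
  const int N = dout.nrow(), C = dout.ncol(), P = H * W;
  NumericVector dx((R_xlen_t)N * P * C);
  dx.attr("dim") = IntegerVector::create(N, H, W, C);
  double* p = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int q = 0; q < P; ++q) {
      double* dst = p + (R_xlen_t)N * (q + (R_xlen_t)P * c);
      for (int n = 0; n < N; ++n) dst[n] = dout(n, c) / P;
    }
  return dx;
}
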