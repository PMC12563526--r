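#include <Rcpp.h>
using namespace Rcpp;

// NHWC convolution support. Arrays are R arrays with dim (N, H, W, C),
// column-major, so element (n,h,w,c) sits at n + N*(h + H*(w + W*c)).
// Padding follows the "same" rule: Hout = ceil(H / stride), zeros split
// evenly with the extra row/column at the end.

static inline void same_geom(int len, int k, int s, int& out, int& pad0) {
  out = (len + s - 1) / s;
  int pad = std::max(0, (out - 1) * s + k - len);
  pad0 = pad / 2;
}

// [[Rcpp::export]]
List im2col_nhwc(NumericVector x, int kh, int kw, int sh, int sw) {
  IntegerVector dm = x.attr("dim");
  const int N = dm[0], H = dm[1], W = dm[2], C = dm[3];
  int Hout, Wout, pt, pl;
  same_geom(H, kh, sh, Hout, pt);
  same_geom(W, kw, sw, Wout, pl);
  const int P = Hout * Wout, T = kh * kw;
  NumericMatrix col((R_xlen_t)N * P, (R_xlen_t)T * C);
  const double* xp = x.begin();
  double* cp = col.begin();
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < kw; ++b)
      for (int a = 0; a < kh; ++a) {
        const int t = a + kh * b;
        const R_xlen_t colbase = (R_xlen_t)(t + (R_xlen_t)T * c) * N * P;
        for (int j = 0; j < Wout; ++j) {
          const int wi = j * sw + b - pl;
          for (int i = 0; i < Hout; ++i) {
            const int hi = i * sh + a - pt;
            double* dst = cp + colbase + (R_xlen_t)N * (i + (R_xlen_t)Hout * j);
            if (hi >= 0 && hi < H && wi >= 0 && wi < W) {
              const double* src = xp + (R_xlen_t)N * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * c));
              std::copy(src, src + N, dst);
            }
          }
        }
      }
  return List::create(_["col"] = col, _["Hout"] = Hout, _["Wout"] = Wout);
}

// scatter-add of the column gradient back onto the input array
// [[Rcpp::export]]
NumericVector col2im_nhwc(NumericMatrix dcol, int N, int H, int W, int C,
                          int kh, int kw, int sh, int sw) {
  int Hout, Wout, pt, pl;
  same_geom(H, kh, sh, Hout, pt);
  same_geom(W, kw, sw, Wout, pl);
  const int T = kh * kw, P = Hout * Wout;
  NumericVector dx((R_xlen_t)N * H * W * C);
  dx.attr("dim") = IntegerVector::create(N, H, W, C);
  double* dxp = dx.begin();
  const double* cp = dcol.begin();
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < kw; ++b)
      for (int a = 0; a < kh; ++a) {
        const int t = a + kh * b;
        const R_xlen_t colbase = (R_xlen_t)(t + (R_xlen_t)T * c) * N * P;
        for (int j = 0; j < Wout; ++j) {
          const int wi = j * sw + b - pl;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < Hout; ++i) {
            const int hi = i * sh + a - pt;
            if (hi < 0 || hi >= H) continue;
            const double* src = cp + colbase + (R_xlen_t)N * (i + (R_xlen_t)Hout * j);
            double* dst = dxp + (R_xlen_t)N * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * c));
            for (int n = 0; n < N; ++n) dst[n] += src[n];
          }
        }
      }
  return dx;
}

// depthwise k x k convolution, stride (sh, sw), same padding
// w: (k*k) x C matrix, tap index a + k*b in rows; b: length-C bias
// [[Rcpp::export]]
NumericVector dwconv_fwd(NumericVector x, NumericMatrix w, NumericVector bias,
                         int k, int sh, int sw) {
  IntegerVector dm = x.attr("dim");
  const int N = dm[0], H = dm[1], W = dm[2], C = dm[3];
  int Hout, Wout, pt, pl;
  same_geom(H, k, sh, Hout, pt);
  same_geom(W, k, sw, Wout, pl);
  NumericVector out((R_xlen_t)N * Hout * Wout * C);
  out.attr("dim") = IntegerVector::create(N, Hout, Wout, C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double bc = bias[c];
    for (int j = 0; j < Wout; ++j)
      for (int i = 0; i < Hout; ++i) {
        double* dst = op + (R_xlen_t)N * (i + (R_xlen_t)Hout * (j + (R_xlen_t)Wout * c));
        for (int n = 0; n < N; ++n) dst[n] = bc;
      }
    for (int b = 0; b < k; ++b)
      for (int a = 0; a < k; ++a) {
        const double wv = w(a + k * b, c);
        if (wv == 0.0) continue;
        // branch-free valid output ranges for this tap
        const int i0 = std::max(0, (pt - a + sh - 1) / sh);
        const int ni = H - 1 - a + pt, nj = W - 1 - b + pl;
        const int i1 = ni < 0 ? -1 : std::min(Hout - 1, ni / sh);
        const int j0 = std::max(0, (pl - b + sw - 1) / sw);
        const int j1 = nj < 0 ? -1 : std::min(Wout - 1, nj / sw);
        for (int j = j0; j <= j1; ++j) {
          const int wi = j * sw + b - pl;
          for (int i = i0; i <= i1; ++i) {
            const int hi = i * sh + a - pt;
            const double* src = xp + (R_xlen_t)N * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * c));
            double* dst = op + (R_xlen_t)N * (i + (R_xlen_t)Hout * (j + (R_xlen_t)Wout * c));
            for (int n = 0; n < N; ++n) dst[n] += wv * src[n];
          }
        }
      }
  }
  return out;
}

// [[Rcpp::export]]
List dwconv_bwd(NumericVector x, NumericMatrix w, NumericVector dout,
                int k, int sh, int sw) {
  IntegerVector dm = x.attr("dim");
  const int N = dm[0], H = dm[1], W = dm[2], C = dm[3];
  int Hout, Wout, pt, pl;
  same_geom(H, k, sh, Hout, pt);
  same_geom(W, k, sw, Wout, pl);
  NumericMatrix dw(k * k, C);
  NumericVector db(C);
  NumericVector dx((R_xlen_t)N * H * W * C);
  dx.attr("dim") = IntegerVector::create(N, H, W, C);
  const double* xp = x.begin();
  const double* dop = dout.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    double dbc = 0.0;
    for (int j = 0; j < Wout; ++j)
      for (int i = 0; i < Hout; ++i) {
        const double* g = dop + (R_xlen_t)N * (i + (R_xlen_t)Hout * (j + (R_xlen_t)Wout * c));
        for (int n = 0; n < N; ++n) dbc += g[n];
      }
    db[c] = dbc;
    for (int b = 0; b < k; ++b)
      for (int a = 0; a < k; ++a) {
        const double wv = w(a + k * b, c);
        double dwv = 0.0;
        const int i0 = std::max(0, (pt - a + sh - 1) / sh);
        const int ni = H - 1 - a + pt, nj = W - 1 - b + pl;
        const int i1 = ni < 0 ? -1 : std::min(Hout - 1, ni / sh);
        const int j0 = std::max(0, (pl - b + sw - 1) / sw);
        const int j1 = nj < 0 ? -1 : std::min(Wout - 1, nj / sw);
        for (int j = j0; j <= j1; ++j) {
          const int wi = j * sw + b - pl;
          for (int i = i0; i <= i1; ++i) {
            const int hi = i * sh + a - pt;
            const double* src = xp + (R_xlen_t)N * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * c));
            const double* g = dop + (R_xlen_t)N * (i + (R_xlen_t)Hout * (j + (R_xlen_t)Wout * c));
            double* dst = dxp + (R_xlen_t)N * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * c));
            // split loops: the axpy vectorizes freely, the reduction uses
            // unrolled accumulators
            for (int n = 0; n < N; ++n) dst[n] += wv * g[n];
            double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
            int n = 0;
            for (; n + 4 <= N; n += 4) {
              a0 += src[n] * g[n];
              a1 += src[n + 1] * g[n + 1];
              a2 += src[n + 2] * g[n + 2];
              a3 += src[n + 3] * g[n + 3];
            }
            dwv += (a0 + a1) + (a2 + a3);
            for (; n < N; ++n) dwv += src[n] * g[n];
          }
        }
        dw(a + k * b, c) = dwv;
      }
  }
  return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx);
}
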