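// Hot loops of the desk-scale network and the geometric warps:
// 3x3 same-padding convolution (forward/backward) on (H, W, N, C) batch
// arrays via im2col + BLAS dgemm, and bilinear sampling at fractional
// positions. Single-threaded and deterministic.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Fill the im2col patch matrix P (HWN x 9C); column r = i + 3j + 9c holds
// X[h+di, w+dj, n, c] (0-padded), rows ordered h, then w, then n.
static void im2col(const double *X, int H, int Wd, int N, int C, double *P) {
  const R_xlen_t HWN = (R_xlen_t)H * Wd * N;
  for (int c = 0; c < C; c++) {
    for (int j = 0; j < 3; j++) {
      const int dj = j - 1;
      for (int i = 0; i < 3; i++) {
        const int di = i - 1;
        double *pc = P + (R_xlen_t)(i + 3 * j + 9 * c) * HWN;
        const int h0 = std::max(0, -di), h1 = H - 1 - std::max(0, di);
        for (int n = 0; n < N; n++) {
          for (int w = 0; w < Wd; w++) {
            double *dst = pc + ((R_xlen_t)n * Wd + w) * H;
            const int ws = w + dj;
            if (ws < 0 || ws >= Wd) { std::memset(dst, 0, H * sizeof(double)); continue; }
            const double *src = X + ((R_xlen_t)(c * N + n) * Wd + ws) * H + di;
            if (h0 > 0) dst[0] = 0.0;
            for (int h = h0; h <= h1; h++) dst[h] = src[h];
            if (h1 < H - 1) dst[H - 1] = 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add of dP back onto the input gradient (transpose of im2col).
static void col2im_add(const double *dP, int H, int Wd, int N, int C,
                       double *dX) {
  const R_xlen_t HWN = (R_xlen_t)H * Wd * N;
  for (int c = 0; c < C; c++) {
    for (int j = 0; j < 3; j++) {
      const int dj = j - 1;
      for (int i = 0; i < 3; i++) {
        const int di = i - 1;
        const double *pc = dP + (R_xlen_t)(i + 3 * j + 9 * c) * HWN;
        const int h0 = std::max(0, -di), h1 = H - 1 - std::max(0, di);
        for (int n = 0; n < N; n++) {
          for (int w = 0; w < Wd; w++) {
            const int ws = w + dj;
            if (ws < 0 || ws >= Wd) continue;
            const double *src = pc + ((R_xlen_t)n * Wd + w) * H;
            double *dst = dX + ((R_xlen_t)(c * N + n) * Wd + ws) * H + di;
            for (int h = h0; h <= h1; h++) dst[h] += src[h];
          }
        }
      }
    }
  }
}

static void gemm(char ta, char tb, int m, int n, int k, const double *A,
                 int lda, const double *B, int ldb, double beta, double *Cm) {
  const double one = 1.0;
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &one, A, &lda, B, &ldb, &beta, Cm,
                  &m FCONE FCONE);
}

// [[Rcpp::export]]
NumericVector conv3_fwd_cpp(NumericVector X, IntegerVector xdim,
                            NumericVector W, NumericVector b) {
  const int H = xdim[0], Wd = xdim[1], N = xdim[2], C = xdim[3];
  const int K = b.size();
  const R_xlen_t HWN = (R_xlen_t)H * Wd * N;
  NumericVector out(HWN * K);
  std::vector<double> P((size_t)HWN * 9 * C);
  im2col(X.begin(), H, Wd, N, C, P.data());
  double *op = out.begin();
  for (int k = 0; k < K; k++)
    for (R_xlen_t t = 0; t < HWN; t++) op[(R_xlen_t)k * HWN + t] = b[k];
  // out (HWN x K) += P (HWN x 9C) * W (9C x K)
  gemm('N', 'N', (int)HWN, K, 9 * C, P.data(), (int)HWN, W.begin(), 9 * C,
       1.0, op);
  out.attr("dim") = IntegerVector::create(H, Wd, N, K);
  return out;
}

// [[Rcpp::export]]
List conv3_bwd_cpp(NumericVector dOut, NumericVector X, IntegerVector xdim,
                   NumericVector W, int K) {
  const int H = xdim[0], Wd = xdim[1], N = xdim[2], C = xdim[3];
  const R_xlen_t HWN = (R_xlen_t)H * Wd * N;
  NumericVector dX(HWN * C);
  NumericVector dW(W.size());
  NumericVector db(K);
  std::vector<double> P((size_t)HWN * 9 * C);
  im2col(X.begin(), H, Wd, N, C, P.data());
  // dW (9C x K) = P^T (9C x HWN) * dOut (HWN x K)
  gemm('T', 'N', 9 * C, K, (int)HWN, P.data(), (int)HWN, dOut.begin(),
       (int)HWN, 0.0, dW.begin());
  // reuse P as dP (HWN x 9C) = dOut (HWN x K) * W^T (K x 9C)
  {
    const double one = 1.0, zero = 0.0;
    const char nt = 'N', tt = 'T';
    const int m = (int)HWN, n = 9 * C;
    F77_CALL(dgemm)(&nt, &tt, &m, &n, &K, &one, dOut.begin(), &m, W.begin(),
                    &n, &zero, P.data(), &m FCONE FCONE);
  }
  col2im_add(P.data(), H, Wd, N, C, dX.begin());
  const double *dop = dOut.begin();
  for (int k = 0; k < K; k++) {
    double acc = 0.0;
    for (R_xlen_t t = 0; t < HWN; t++) acc += dop[(R_xlen_t)k * HWN + t];
    db[k] = acc;
  }
  dX.attr("dim") = xdim;
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector bilinear_cpp(NumericMatrix X, NumericVector rpos,
                           NumericVector cpos, double fill) {
  const int n = X.nrow(), m = X.ncol();
  const R_xlen_t len = rpos.size();
  NumericVector out(len);
  const double *xp = X.begin();
  for (R_xlen_t t = 0; t < len; t++) {
    const double r = rpos[t], c = cpos[t];
    if (r < 1.0 || r > n || c < 1.0 || c > m) { out[t] = fill; continue; }
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    if (r0 > n - 1) r0 = n - 1;
    if (c0 > m - 1) c0 = m - 1;
    const double fr = r - r0, fc = c - c0;
    const double *base = xp + (R_xlen_t)(c0 - 1) * n + (r0 - 1);
    out[t] = base[0] * (1 - fr) * (1 - fc) + base[1] * fr * (1 - fc) +
             base[n] * (1 - fr) * fc + base[n + 1] * fr * fc;
  }
  return out;
}
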