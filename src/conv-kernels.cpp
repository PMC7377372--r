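// Convolution kernels for the strand-scan layers.
//
// The batch tensor layout is column-major B x S x C (batch fastest), so for
// a fixed kernel offset m and channel c the im2col column is one contiguous
// block of the input (a memcpy) and its adjoint is one contiguous add. The
// gathered matrix is multiplied with the flattened kernel stack through
// BLAS dgemm; the backward pass rebuilds the gather instead of caching it,
// trading a cheap memcpy for a large resident buffer.
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

static void gather(const double *x, double *z, int B, int S, int C, int M) {
  const int L = S - M + 1;
  const size_t n = (size_t)B * L;
  for (int c = 0; c < C; ++c)
    for (int m = 0; m < M; ++m)
      std::memcpy(z + ((size_t)c * M + m) * n,
                  x + (size_t)c * B * S + (size_t)m * B,
                  sizeof(double) * n);
}

// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericVector X, IntegerVector dims, int M) {
  const int B = dims[0], S = dims[1], C = dims[2];
  const int L = S - M + 1;
  NumericMatrix Z(B * L, M * C);
  gather(REAL(X), REAL(Z), B, S, C, M);
  return Z;
}

// [[Rcpp::export(name = ".col2im_cpp")]]
NumericVector col2im_cpp(NumericMatrix dZ, IntegerVector dims, int M) {
  const int B = dims[0], S = dims[1], C = dims[2];
  const int L = S - M + 1;
  const size_t n = (size_t)B * L;
  NumericVector dX((size_t)B * S * C);
  const double *z = REAL(dZ);
  double *x = REAL(dX);
  for (int c = 0; c < C; ++c)
    for (int m = 0; m < M; ++m) {
      const double *src = z + ((size_t)c * M + m) * n;
      double *dst = x + (size_t)c * B * S + (size_t)m * B;
      for (size_t j = 0; j < n; ++j) dst[j] += src[j];
    }
  dX.attr("dim") = dims;
  return dX;
}

// VALID cross-correlation: X (B x S x C) * Wmat ((M*C) x K) -> (B x L x K).
// [[Rcpp::export(name = ".conv_fwd_cpp")]]
NumericVector conv_fwd_cpp(NumericVector X, NumericMatrix Wmat,
                           IntegerVector dims, int M) {
  const int B = dims[0], S = dims[1], C = dims[2];
  const int L = S - M + 1;
  const int K = Wmat.ncol(), MC = Wmat.nrow();
  const int BL = B * L;
  std::vector<double> Z((size_t)BL * MC);
  gather(REAL(X), Z.data(), B, S, C, M);
  NumericVector out((size_t)BL * K);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &BL, &K, &MC, &one, Z.data(), &BL,
                  REAL(Wmat), &MC, &zero, REAL(out), &BL FCONE FCONE);
  out.attr("dim") = IntegerVector::create(B, L, K);
  return out;
}

// Backward of the VALID cross-correlation: given dA (B x L x K) returns
// dW ((M*C) x K) and, when need_dx, dX (B x S x C).
// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(NumericVector X, NumericMatrix Wmat, NumericVector dA,
                  IntegerVector dims, int M, bool need_dx) {
  const int B = dims[0], S = dims[1], C = dims[2];
  const int L = S - M + 1;
  const int K = Wmat.ncol(), MC = Wmat.nrow();
  const int BL = B * L;
  std::vector<double> Z((size_t)BL * MC);
  gather(REAL(X), Z.data(), B, S, C, M);
  NumericMatrix dW(MC, K);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("T", "N", &MC, &K, &BL, &one, Z.data(), &BL,
                  REAL(dA), &BL, &zero, REAL(dW), &MC FCONE FCONE);
  if (!need_dx) return List::create(_["dW"] = dW);
  std::vector<double> dZ((size_t)BL * MC);
  F77_CALL(dgemm)("N", "T", &BL, &MC, &K, &one, REAL(dA), &BL,
                  REAL(Wmat), &MC, &zero, dZ.data(), &BL FCONE FCONE);
  NumericVector dX((size_t)B * S * C);
  double *x = REAL(dX);
  const size_t n = (size_t)BL;
  for (int c = 0; c < C; ++c)
    for (int m = 0; m < M; ++m) {
      const double *src = dZ.data() + ((size_t)c * M + m) * n;
      double *dst = x + (size_t)c * B * S + (size_t)m * B;
      for (size_t j = 0; j < n; ++j) dst[j] += src[j];
    }
  dX.attr("dim") = dims;
  return List::create(_["dW"] = dW, _["dX"] = dX);
}

// Rectifier, preserving dim.
// [[Rcpp::export(name = ".relu_cpp")]]
NumericVector relu_cpp(NumericVector x) {
  NumericVector out = clone(x);
  double *o = REAL(out);
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (o[i] < 0) o[i] = 0;
  return out;
}

// Elementwise dR * (A > 0) without materializing the logical mask.
// [[Rcpp::export(name = ".relu_backward_cpp")]]
NumericVector relu_backward_cpp(NumericVector dR, NumericVector A) {
  NumericVector out = clone(dR);
  double *o = REAL(out);
  const double *a = REAL(A);
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (a[i] <= 0) o[i] = 0;
  return out;
}

// Non-overlapping max pooling along the position axis of (B x L x K);
// trailing positions beyond p * floor(L/p) are dropped. Returns the pooled
// values and the within-window argmax (1-based) for the backward pass.
// [[Rcpp::export(name = ".pool_max_cpp")]]
List pool_max_cpp(NumericVector X, IntegerVector dims, int p) {
  const int B = dims[0], L = dims[1], K = dims[2];
  const int Lp = L / p;
  NumericVector out((size_t)B * Lp * K);
  IntegerVector amax((size_t)B * Lp * K);
  const double *x = REAL(X);
  double *o = REAL(out);
  int *a = INTEGER(amax);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < Lp; ++j)
      for (int b = 0; b < B; ++b) {
        const size_t base = (size_t)k * B * L + (size_t)j * p * B + b;
        double best = x[base];
        int bq = 1;
        for (int q = 1; q < p; ++q) {
          const double v = x[base + (size_t)q * B];
          if (v > best) { best = v; bq = q + 1; }
        }
        const size_t oi = (size_t)k * B * Lp + (size_t)j * B + b;
        o[oi] = best;
        a[oi] = bq;
      }
  out.attr("dim") = IntegerVector::create(B, Lp, K);
  amax.attr("dim") = IntegerVector::create(B, Lp, K);
  return List::create(_["out"] = out, _["amax"] = amax);
}

// Adjoint of max pooling: route each pooled gradient to its argmax slot.
// [[Rcpp::export(name = ".pool_max_bwd_cpp")]]
NumericVector pool_max_bwd_cpp(NumericVector dOut, IntegerVector amax,
                               IntegerVector dims, int p, int in_len) {
  const int B = dims[0], Lp = dims[1], K = dims[2];
  NumericVector dX((size_t)B * in_len * K);
  const double *g = REAL(dOut);
  const int *a = INTEGER(amax);
  double *x = REAL(dX);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < Lp; ++j)
      for (int b = 0; b < B; ++b) {
        const size_t oi = (size_t)k * B * Lp + (size_t)j * B + b;
        x[(size_t)k * B * in_len + ((size_t)j * p + a[oi] - 1) * B + b] +=
          g[oi];
      }
  dX.attr("dim") = IntegerVector::create(B, in_len, K);
  return dX;
}
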