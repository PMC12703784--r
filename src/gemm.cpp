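// BLAS-backed matrix products writing into preallocated buffers, so the
// training loop's large intermediates are reused across iterations
// instead of churning the garbage collector.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// C (m x n) = A (m x k) %*% t(B) (k x n), B given as (n x k)
// [[Rcpp::export]]
void cpp_gemm_abt_into(NumericVector A, int m, int k, NumericMatrix B,
                       NumericVector bias, NumericVector C) {
  int n = B.nrow();
  double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "T", &m, &n, &k, &one, A.begin(), &m, B.begin(),
                  &n, &zero, C.begin(), &m FCONE FCONE);
  if (bias.size() == n) {
    double *pc = C.begin();
    for (int j = 0; j < n; ++j) {
      const double b = bias[j];
      double *col = pc + (R_xlen_t)j * m;
      for (int i = 0; i < m; ++i) col[i] += b;
    }
  }
}

// C (m x n) = A (m x k) %*% B (k x n)
// [[Rcpp::export]]
void cpp_gemm_ab_into(NumericVector A, int m, int k, NumericMatrix B,
                      NumericVector C) {
  int n = B.ncol();
  double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &m, &n, &k, &one, A.begin(), &m, B.begin(),
                  &k, &zero, C.begin(), &m FCONE FCONE);
}

// C (k x n) = t(A) (k x m) %*% B (m x n); A given as (m x k)
// [[Rcpp::export]]
NumericMatrix cpp_gemm_atb(NumericVector A, int m, int k, NumericVector B,
                           int n) {
  NumericMatrix C(k, n);
  double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("T", "N", &k, &n, &m, &one, A.begin(), &m, B.begin(),
                  &m, &zero, C.begin(), &k FCONE FCONE);
  return C;
}

// column sums of an (m x n) matrix given as a vector
// [[Rcpp::export]]
NumericVector cpp_colsums(NumericVector A, int m, int n) {
  NumericVector out(n);
  const double *pa = A.begin();
  for (int j = 0; j < n; ++j) {
    double s = 0;
    const double *col = pa + (R_xlen_t)j * m;
    for (int i = 0; i < m; ++i) s += col[i];
    out[j] = s;
  }
  return out;
}
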