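// Hot elementwise kernels of the training loop: moment injection (the
// adaptive-instance-normalization transform) with its exact backward pass,
// the relu backward mask, and fused softmax cross-entropy with an ignore
// label. Feature maps are (H, W, B, C) column-major so every (b, c)
// channel plane is one contiguous block of H*W doubles.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// out = sigma_t * (f - mu(f)) / sigma(f) + mu_t with per-plane moments;
// population variance, sigma = sqrt(var + eps^2)
// [[Rcpp::export]]
List cpp_inject_fwd(NumericVector f, int n, int BC, NumericVector mu_t,
                    NumericVector sigma_t, double eps) {
  NumericVector out(no_init(f.size()));
  NumericVector xhat(no_init(f.size()));
  NumericVector mu(BC), sigma(BC);
  const double *pf = f.begin();
  double *po = out.begin(), *px = xhat.begin();
  for (int p = 0; p < BC; ++p) {
    const double *src = pf + (R_xlen_t)p * n;
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += src[i]; s2 += src[i] * src[i]; }
    const double m = s / n;
    double v = s2 / n - m * m;
    if (v < 0) v = 0;
    const double sd = std::sqrt(v + eps * eps);
    mu[p] = m; sigma[p] = sd;
    const double inv = 1.0 / sd;
    const double a = sigma_t[p], b = mu_t[p];
    double *o = po + (R_xlen_t)p * n, *xh = px + (R_xlen_t)p * n;
    for (int i = 0; i < n; ++i) {
      const double z = (src[i] - m) * inv;
      xh[i] = z;
      o[i] = a * z + b;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mu"] = mu,
                      _["sigma"] = sigma);
}

// gradients wrt the content map and the injected target statistics
// [[Rcpp::export]]
List cpp_inject_bwd(NumericVector dout, NumericVector xhat, int n, int BC,
                    NumericVector sigma, NumericVector sigma_t) {
  NumericVector dx(no_init(dout.size()));
  NumericVector dmu_t(BC), dsigma_t(BC);
  const double *pd = dout.begin(), *px = xhat.begin();
  double *pdx = dx.begin();
  for (int p = 0; p < BC; ++p) {
    const double *d = pd + (R_xlen_t)p * n;
    const double *xh = px + (R_xlen_t)p * n;
    double sd_ = 0, sdx = 0;
    for (int i = 0; i < n; ++i) { sd_ += d[i]; sdx += d[i] * xh[i]; }
    dmu_t[p] = sd_;
    dsigma_t[p] = sdx;
    const double g = sigma_t[p], inv = 1.0 / sigma[p];
    // exact backward through the instance normalization of f (with
    // xhat = (f - mu)/sigma, sigma^2 = var + eps^2):
    // dx = (g/sigma) * (d - mean(d) - xhat * mean(d * xhat))
    const double mean_d = sd_ / n;
    const double mean_dx = sdx / n;
    double *o = pdx + (R_xlen_t)p * n;
    for (int i = 0; i < n; ++i)
      o[i] = g * inv * (d[i] - mean_d - xh[i] * mean_dx);
  }
  return List::create(_["dx"] = dx, _["dmu_t"] = dmu_t,
                      _["dsigma_t"] = dsigma_t);
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dout, NumericVector x) {
  NumericVector dx(no_init(dout.size()));
  const double *pd = dout.begin(), *px = x.begin();
  double *po = dx.begin();
  const R_xlen_t N = dout.size();
  for (R_xlen_t i = 0; i < N; ++i) po[i] = px[i] > 0 ? pd[i] : 0.0;
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector out(no_init(x.size()));
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t N = x.size();
  for (R_xlen_t i = 0; i < N; ++i) po[i] = px[i] > 0 ? px[i] : 0.0;
  return out;
}

// fused pixel softmax cross-entropy with ignore label; scores is the
// (N, K) pixel matrix, y holds 1-based class indices (ignore + 1 marks
// excluded pixels). Returns the mean loss over valid pixels and its
// gradient in one pass.
// [[Rcpp::export]]
List cpp_ce(NumericMatrix scores, IntegerVector y, int ignore1) {
  const int N = scores.nrow(), K = scores.ncol();
  NumericMatrix grad(N, K);
  const double *ps = scores.begin();
  double *pg = grad.begin();
  double loss = 0;
  R_xlen_t nvalid = 0;
  std::vector<double> row(K);
  for (int i = 0; i < N; ++i) {
    if (y[i] == ignore1) continue;
    double m = ps[i];
    for (int k = 1; k < K; ++k) {
      const double v = ps[i + (R_xlen_t)k * N];
      if (v > m) m = v;
    }
    double z = 0;
    for (int k = 0; k < K; ++k) {
      row[k] = std::exp(ps[i + (R_xlen_t)k * N] - m);
      z += row[k];
    }
    const double lse = m + std::log(z);
    loss += lse - ps[i + (R_xlen_t)(y[i] - 1) * N];
    ++nvalid;
    for (int k = 0; k < K; ++k)
      pg[i + (R_xlen_t)k * N] = row[k] / z;
    pg[i + (R_xlen_t)(y[i] - 1) * N] -= 1.0;
  }
  if (nvalid == 0) return List::create(_["loss"] = R_NaReal);
  const double inv = 1.0 / nvalid;
  for (R_xlen_t i = 0; i < (R_xlen_t)N * K; ++i) pg[i] *= inv;
  return List::create(_["loss"] = loss / nvalid, _["grad"] = grad);
}
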