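// Patch gather/scatter for the 3x3 (pad 1) convolutions. Feature maps are
// (H, W, B, C) column-major; the column matrix has one row per output
// pixel (i, j, b) and kernel-offset-major / channel-minor columns, so the
// convolution itself is a single BLAS GEMM on the R side.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int B, int C,
                         int stride) {
  const int Ho = (H - 1) / stride + 1;
  const int Wo = (W - 1) / stride + 1;
  const R_xlen_t N = (R_xlen_t)Ho * Wo * B;
  NumericMatrix M(N, C * 9);
  const double *px = x.begin();
  double *pm = M.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int kx = 0; kx < 3; ++kx) {
    for (int ky = 0; ky < 3; ++ky) {
      const int k = kx * 3 + ky;
      for (int c = 0; c < C; ++c) {
        double *col = pm + ((R_xlen_t)(k * C + c)) * N;
        for (int b = 0; b < B; ++b) {
          const double *plane = px + ((R_xlen_t)(c * B + b)) * planeHW;
          for (int j = 0; j < Wo; ++j) {
            const int sw = j * stride + kx - 1;  // source column
            double *dst = col + ((R_xlen_t)(b * Wo + j)) * Ho;
            if (sw < 0 || sw >= W) {
              for (int i = 0; i < Ho; ++i) dst[i] = 0.0;
              continue;
            }
            const double *srccol = plane + (R_xlen_t)sw * H;
            for (int i = 0; i < Ho; ++i) {
              const int sh = i * stride + ky - 1;  // source row
              dst[i] = (sh < 0 || sh >= H) ? 0.0 : srccol[sh];
            }
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dM, int H, int W, int B, int C,
                         int stride) {
  const int Ho = (H - 1) / stride + 1;
  const int Wo = (W - 1) / stride + 1;
  const R_xlen_t N = (R_xlen_t)Ho * Wo * B;
  NumericVector dx((R_xlen_t)H * W * B * C);
  const double *pm = dM.begin();
  double *px = dx.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int kx = 0; kx < 3; ++kx) {
    for (int ky = 0; ky < 3; ++ky) {
      const int k = kx * 3 + ky;
      for (int c = 0; c < C; ++c) {
        const double *col = pm + ((R_xlen_t)(k * C + c)) * N;
        for (int b = 0; b < B; ++b) {
          double *plane = px + ((R_xlen_t)(c * B + b)) * planeHW;
          for (int j = 0; j < Wo; ++j) {
            const int sw = j * stride + kx - 1;
            if (sw < 0 || sw >= W) continue;
            const double *src = col + ((R_xlen_t)(b * Wo + j)) * Ho;
            double *dstcol = plane + (R_xlen_t)sw * H;
            for (int i = 0; i < Ho; ++i) {
              const int sh = i * stride + ky - 1;
              if (sh >= 0 && sh < H) dstcol[sh] += src[i];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, B, C);
  return dx;
}

// nearest-neighbour upsampling of an (H, W, B, C) map by an integer factor
// [[Rcpp::export]]
NumericVector cpp_upsample(NumericVector x, int H, int W, int BC,
                           int factor) {
  const int Ho = H * factor, Wo = W * factor;
  NumericVector out(no_init((R_xlen_t)Ho * Wo * BC));
  const double *px = x.begin();
  double *po = out.begin();
  for (int p = 0; p < BC; ++p) {
    const double *src = px + (R_xlen_t)p * H * W;
    double *dst = po + (R_xlen_t)p * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      const double *scol = src + (R_xlen_t)(j / factor) * H;
      double *dcol = dst + (R_xlen_t)j * Ho;
      for (int i = 0; i < Ho; ++i) dcol[i] = scol[i / factor];
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, BC, 1);
  return out;
}

// gradient of cpp_upsample: sum over each factor x factor block
// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector dout, int Ho, int Wo, int BC,
                               int factor) {
  const int H = Ho / factor, W = Wo / factor;
  NumericVector dx((R_xlen_t)H * W * BC);
  const double *pd = dout.begin();
  double *px = dx.begin();
  for (int p = 0; p < BC; ++p) {
    const double *src = pd + (R_xlen_t)p * Ho * Wo;
    double *dst = px + (R_xlen_t)p * H * W;
    for (int j = 0; j < Wo; ++j) {
      const double *scol = src + (R_xlen_t)j * Ho;
      double *dcol = dst + (R_xlen_t)(j / factor) * H;
      for (int i = 0; i < Ho; ++i) dcol[i / factor] += scol[i];
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, BC, 1);
  return dx;
}

// in-place variants used by the training loop's preallocated workspaces:
// contents of `M` / `dx` are overwritten, their dims are fixed at creation

// [[Rcpp::export]]
void cpp_im2col_into(NumericVector M, NumericVector x, int H, int W, int B,
                     int C, int stride) {
  const int Ho = (H - 1) / stride + 1;
  const int Wo = (W - 1) / stride + 1;
  const R_xlen_t N = (R_xlen_t)Ho * Wo * B;
  const double *px = x.begin();
  double *pm = M.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int kx = 0; kx < 3; ++kx) {
    for (int ky = 0; ky < 3; ++ky) {
      const int k = kx * 3 + ky;
      for (int c = 0; c < C; ++c) {
        double *col = pm + ((R_xlen_t)(k * C + c)) * N;
        for (int b = 0; b < B; ++b) {
          const double *plane = px + ((R_xlen_t)(c * B + b)) * planeHW;
          for (int j = 0; j < Wo; ++j) {
            const int sw = j * stride + kx - 1;
            double *dst = col + ((R_xlen_t)(b * Wo + j)) * Ho;
            if (sw < 0 || sw >= W) {
              for (int i = 0; i < Ho; ++i) dst[i] = 0.0;
              continue;
            }
            const double *srccol = plane + (R_xlen_t)sw * H;
            for (int i = 0; i < Ho; ++i) {
              const int sh = i * stride + ky - 1;
              dst[i] = (sh < 0 || sh >= H) ? 0.0 : srccol[sh];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
void cpp_col2im_into(NumericVector dx, NumericVector dM, int H, int W,
                     int B, int C, int stride) {
  const int Ho = (H - 1) / stride + 1;
  const int Wo = (W - 1) / stride + 1;
  const R_xlen_t N = (R_xlen_t)Ho * Wo * B;
  double *px = dx.begin();
  const double *pm = dM.begin();
  std::fill(px, px + (R_xlen_t)H * W * B * C, 0.0);
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int kx = 0; kx < 3; ++kx) {
    for (int ky = 0; ky < 3; ++ky) {
      const int k = kx * 3 + ky;
      for (int c = 0; c < C; ++c) {
        const double *col = pm + ((R_xlen_t)(k * C + c)) * N;
        for (int b = 0; b < B; ++b) {
          double *plane = px + ((R_xlen_t)(c * B + b)) * planeHW;
          for (int j = 0; j < Wo; ++j) {
            const int sw = j * stride + kx - 1;
            if (sw < 0 || sw >= W) continue;
            const double *src = col + ((R_xlen_t)(b * Wo + j)) * Ho;
            double *dstcol = plane + (R_xlen_t)sw * H;
            for (int i = 0; i < Ho; ++i) {
              const int sh = i * stride + ky - 1;
              if (sh >= 0 && sh < H) dstcol[sh] += src[i];
            }
          }
        }
      }
    }
  }
}
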