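// Fused training-time augmentation of one (H, W, 3) image and its label
// mask: horizontal flip + rotation by inverse mapping (bilinear for the
// image with black fill, nearest for the mask with ignore fill), then
// brightness/contrast/saturation/hue jitter. The random factors are drawn
// on the R side so the draw sequence stays under R's RNG.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clamp01(double v) {
  return v < 0 ? 0 : (v > 1 ? 1 : v);
}

// [[Rcpp::export]]
List cpp_augment(NumericVector image, IntegerVector mask, int H, int W,
                 bool flip, double angle_rad, double fb, double fc,
                 double fs, double dh, int ignore,
                 NumericVector std_mean = NumericVector(0),
                 NumericVector std_sd = NumericVector(0)) {
  NumericVector out(no_init((R_xlen_t)H * W * 3));
  IntegerVector omask(no_init((R_xlen_t)H * W));
  const double *pi = image.begin();
  double *po = out.begin();
  const double cy = (H + 1) / 2.0, cx = (W + 1) / 2.0;
  const double ct = std::cos(angle_rad), st = std::sin(angle_rad);
  const R_xlen_t plane = (R_xlen_t)H * W;

  for (int c = 0; c < W; ++c) {
    const double xo = (c + 1) - cx;
    for (int r = 0; r < H; ++r) {
      const double yo = (r + 1) - cy;
      double sx = ct * xo + st * yo + cx;
      double sy = -st * xo + ct * yo + cy;
      const R_xlen_t o = r + (R_xlen_t)c * H;
      if (sx < 1 || sx > W || sy < 1 || sy > H) {
        po[o] = po[o + plane] = po[o + 2 * plane] = 0.0;
        omask[o] = ignore;
        continue;
      }
      if (flip) sx = W + 1 - sx;
      // bilinear sample (1-based continuous coordinates)
      int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const double fx = sx - x0, fy = sy - y0;
      int x1 = x0 + 1, y1 = y0 + 1;
      if (x0 < 1) x0 = 1; if (x0 > W) x0 = W;
      if (x1 < 1) x1 = 1; if (x1 > W) x1 = W;
      if (y0 < 1) y0 = 1; if (y0 > H) y0 = H;
      if (y1 < 1) y1 = 1; if (y1 > H) y1 = H;
      const R_xlen_t i00 = (y0 - 1) + (R_xlen_t)(x0 - 1) * H;
      const R_xlen_t i10 = (y1 - 1) + (R_xlen_t)(x0 - 1) * H;
      const R_xlen_t i01 = (y0 - 1) + (R_xlen_t)(x1 - 1) * H;
      const R_xlen_t i11 = (y1 - 1) + (R_xlen_t)(x1 - 1) * H;
      const double w00 = (1 - fy) * (1 - fx), w10 = fy * (1 - fx);
      const double w01 = (1 - fy) * fx, w11 = fy * fx;
      for (int ch = 0; ch < 3; ++ch) {
        const double *pl = pi + (R_xlen_t)ch * plane;
        po[o + (R_xlen_t)ch * plane] =
          pl[i00] * w00 + pl[i10] * w10 + pl[i01] * w01 + pl[i11] * w11;
      }
      int xn = (int)std::floor(sx + 0.5), yn = (int)std::floor(sy + 0.5);
      if (xn < 1) xn = 1; if (xn > W) xn = W;
      if (yn < 1) yn = 1; if (yn > H) yn = H;
      omask[o] = mask[(yn - 1) + (R_xlen_t)(xn - 1) * H];
    }
  }

  // photometric jitter: brightness, contrast (blend with the mean gray of
  // the brightened image), saturation (blend with per-pixel gray), then
  // hue rotation in HSV space; clipped to [0, 1]
  double mg = 0;
  for (R_xlen_t i = 0; i < plane; ++i) {
    po[i] *= fb; po[i + plane] *= fb; po[i + 2 * plane] *= fb;
    mg += 0.299 * po[i] + 0.587 * po[i + plane] + 0.114 * po[i + 2 * plane];
  }
  mg /= plane;
  for (R_xlen_t i = 0; i < plane; ++i) {
    double r = mg + fc * (po[i] - mg);
    double g = mg + fc * (po[i + plane] - mg);
    double b = mg + fc * (po[i + 2 * plane] - mg);
    const double gray = 0.299 * r + 0.587 * g + 0.114 * b;
    r = clamp01(gray + fs * (r - gray));
    g = clamp01(gray + fs * (g - gray));
    b = clamp01(gray + fs * (b - gray));
    if (dh != 0) {
      const double mx = std::max(r, std::max(g, b));
      const double mn = std::min(r, std::min(g, b));
      const double d = mx - mn;
      double h = 0;
      if (d > 0) {
        if (mx == r) { h = (g - b) / d; h -= 6.0 * std::floor(h / 6.0); }
        else if (mx == g) h = (b - r) / d + 2.0;
        else h = (r - g) / d + 4.0;
        h /= 6.0;
      }
      const double s = mx > 0 ? d / mx : 0.0;
      h = h + dh; h -= std::floor(h);
      const double h6 = h * 6.0;
      const double cc = mx * s;
      const double h6m2 = h6 - 2.0 * std::floor(h6 / 2.0);
      const double x = cc * (1.0 - std::fabs(h6m2 - 1.0));
      const double m = mx - cc;
      int sec = (int)std::floor(h6); if (sec > 5) sec = 5;
      switch (sec) {
        case 0: r = cc; g = x; b = 0; break;
        case 1: r = x; g = cc; b = 0; break;
        case 2: r = 0; g = cc; b = x; break;
        case 3: r = 0; g = x; b = cc; break;
        case 4: r = x; g = 0; b = cc; break;
        default: r = cc; g = 0; b = x;
      }
      r += m; g += m; b += m;
    }
    po[i] = clamp01(r);
    po[i + plane] = clamp01(g);
    po[i + 2 * plane] = clamp01(b);
  }
  // optional channel standardization fused into the same pass
  if (std_mean.size() == 3) {
    for (int ch = 0; ch < 3; ++ch) {
      double *pl = po + (R_xlen_t)ch * plane;
      const double m = std_mean[ch], sinv = 1.0 / std_sd[ch];
      for (R_xlen_t i = 0; i < plane; ++i) pl[i] = (pl[i] - m) * sinv;
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, 3);
  omask.attr("dim") = IntegerVector::create(H, W);
  return List::create(_["image"] = out, _["mask"] = omask);
}
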