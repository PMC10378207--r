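// Shared image primitives: bilinear resampling, backward-warping by a
// displacement field, and separable Gaussian smoothing. Used by the TV-L1
// pyramid, triplet assembly and the synthetic frame warper so that one
// sampling convention holds package-wide. Matrices are H x W rasters,
// row index = y (down), column index = x (right).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sample_bilinear(const double* img, int H, int W,
                                     double y, double x) {
  // clamp-to-edge (replicate border)
  if (x < 0) x = 0; if (x > W - 1) x = W - 1;
  if (y < 0) y = 0; if (y > H - 1) y = H - 1;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  const double fx = x - x0, fy = y - y0;
  const double a = img[y0 + (size_t)H * x0], b = img[y0 + (size_t)H * x1];
  const double c = img[y1 + (size_t)H * x0], d = img[y1 + (size_t)H * x1];
  return (1 - fy) * ((1 - fx) * a + fx * b) + fy * ((1 - fx) * c + fx * d);
}

// [[Rcpp::export]]
NumericMatrix bilinear_resize(NumericMatrix img, int ho, int wo) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(ho, wo);
  const double sy = (double)H / ho, sx = (double)W / wo;
  for (int j = 0; j < wo; ++j) {
    const double x = (j + 0.5) * sx - 0.5;
    for (int i = 0; i < ho; ++i) {
      const double y = (i + 0.5) * sy - 0.5;
      out(i, j) = sample_bilinear(img.begin(), H, W, y, x);
    }
  }
  return out;
}

// out(i, j) = img(i + v(i,j), j + u(i,j)), bilinear, replicated border.
// [[Rcpp::export]]
NumericMatrix bilinear_warp(NumericMatrix img, NumericMatrix u, NumericMatrix v) {
  const int H = img.nrow(), W = img.ncol();
  if (u.nrow() != H || u.ncol() != W || v.nrow() != H || v.ncol() != W)
    stop("flow field dims must match image");
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = sample_bilinear(img.begin(), H, W, i + v(i, j), j + u(i, j));
  return out;
}

// [[Rcpp::export]]
NumericMatrix gauss_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) {
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + r];
  }
  for (auto& kv : ker) kv /= s;
  NumericMatrix tmp(H, W), out(H, W);
  // vertical pass, reflect borders
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t;
        if (ii < 0) ii = -ii;
        if (ii > H - 1) ii = 2 * (H - 1) - ii;
        acc += ker[t + r] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  // horizontal pass
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int jj = j + t;
        if (jj < 0) jj = -jj;
        if (jj > W - 1) jj = 2 * (W - 1) - jj;
        acc += ker[t + r] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  }
  return out;
}
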