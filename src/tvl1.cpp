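// Duality-based TV-L1 optical flow, single pyramid level.
// Primal-dual scheme: alternate (i) pointwise thresholding of the
// linearized L1 data term, (ii) TV denoising of each flow component via a
// Chambolle-style dual ascent. The R driver owns the coarse-to-fine
// pyramid and flow upscaling.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;

static inline double sample_bl(const mat& img, double y, double x) {
  const int H = img.n_rows, W = img.n_cols;
  if (x < 0) x = 0; if (x > W - 1) x = W - 1;
  if (y < 0) y = 0; if (y > H - 1) y = H - 1;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  const double fx = x - x0, fy = y - y0;
  return (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
         fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
}

static void central_grad(const mat& I, mat& Ix, mat& Iy) {
  const int H = I.n_rows, W = I.n_cols;
  Ix.set_size(H, W); Iy.set_size(H, W);
  for (int j = 0; j < W; ++j) {
    const int jm = std::max(j - 1, 0), jp = std::min(j + 1, W - 1);
    for (int i = 0; i < H; ++i) {
      const int im = std::max(i - 1, 0), ip = std::min(i + 1, H - 1);
      Ix(i, j) = 0.5 * (I(i, jp) - I(i, jm));
      Iy(i, j) = 0.5 * (I(ip, j) - I(im, j));
    }
  }
}

// forward differences with Neumann boundary (last row/col derivative = 0)
static void forward_grad(const mat& u, mat& ux, mat& uy) {
  const int H = u.n_rows, W = u.n_cols;
  ux.zeros(H, W); uy.zeros(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (j < W - 1) ux(i, j) = u(i, j + 1) - u(i, j);
      if (i < H - 1) uy(i, j) = u(i + 1, j) - u(i, j);
    }
}

// divergence adjoint to forward_grad
static void divergence(const mat& p1, const mat& p2, mat& div) {
  const int H = p1.n_rows, W = p1.n_cols;
  div.set_size(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double d = 0;
      d += (j == 0) ? p1(i, 0) : (j == W - 1 ? -p1(i, j - 1) : p1(i, j) - p1(i, j - 1));
      d += (i == 0) ? p2(0, j) : (i == H - 1 ? -p2(i - 1, j) : p2(i, j) - p2(i - 1, j));
      div(i, j) = d;
    }
}

// [[Rcpp::export]]
List tvl1_level(NumericMatrix I0m, NumericMatrix I1m,
                NumericMatrix um, NumericMatrix vm,
                double lambda, double theta, double tau,
                int warps, int maxiter, double epsilon) {
  const int H = I0m.nrow(), W = I0m.ncol();
  mat I0(I0m.begin(), H, W), I1(I1m.begin(), H, W);
  mat u(um.begin(), H, W), v(vm.begin(), H, W);
  mat I1x, I1y;
  central_grad(I1, I1x, I1y);
  mat p11(H, W, arma::fill::zeros), p12(H, W, arma::fill::zeros);
  mat p21(H, W, arma::fill::zeros), p22(H, W, arma::fill::zeros);
  const double l_t = lambda * theta;
  const double taut = tau / theta;
  mat I1w(H, W), I1wx(H, W), I1wy(H, W), grad(H, W), rho_c(H, W);
  mat v1(H, W), v2(H, W), div1(H, W), div2(H, W), ux(H, W), uy(H, W);

  for (int w = 0; w < warps; ++w) {
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double y = i + v(i, j), x = j + u(i, j);
        I1w(i, j) = sample_bl(I1, y, x);
        I1wx(i, j) = sample_bl(I1x, y, x);
        I1wy(i, j) = sample_bl(I1y, y, x);
      }
    grad = I1wx % I1wx + I1wy % I1wy;
    rho_c = I1w - I1wx % u - I1wy % v - I0;

    for (int n = 0; n < maxiter; ++n) {
      double err = 0;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double rho = rho_c(i, j) + I1wx(i, j) * u(i, j) + I1wy(i, j) * v(i, j);
          double d1, d2;
          if (rho < -l_t * grad(i, j)) {
            d1 = l_t * I1wx(i, j); d2 = l_t * I1wy(i, j);
          } else if (rho > l_t * grad(i, j)) {
            d1 = -l_t * I1wx(i, j); d2 = -l_t * I1wy(i, j);
          } else if (grad(i, j) > 1e-10) {
            d1 = -rho * I1wx(i, j) / grad(i, j);
            d2 = -rho * I1wy(i, j) / grad(i, j);
          } else {
            d1 = 0; d2 = 0;
          }
          v1(i, j) = u(i, j) + d1;
          v2(i, j) = v(i, j) + d2;
        }
      divergence(p11, p12, div1);
      divergence(p21, p22, div2);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double un = v1(i, j) + theta * div1(i, j);
          const double vn = v2(i, j) + theta * div2(i, j);
          err += (un - u(i, j)) * (un - u(i, j)) + (vn - v(i, j)) * (vn - v(i, j));
          u(i, j) = un; v(i, j) = vn;
        }
      forward_grad(u, ux, uy);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double ng = 1.0 + taut * std::sqrt(ux(i, j) * ux(i, j) + uy(i, j) * uy(i, j));
          p11(i, j) = (p11(i, j) + taut * ux(i, j)) / ng;
          p12(i, j) = (p12(i, j) + taut * uy(i, j)) / ng;
        }
      forward_grad(v, ux, uy);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double ng = 1.0 + taut * std::sqrt(ux(i, j) * ux(i, j) + uy(i, j) * uy(i, j));
          p21(i, j) = (p21(i, j) + taut * ux(i, j)) / ng;
          p22(i, j) = (p22(i, j) + taut * uy(i, j)) / ng;
        }
      if (err / (H * W) < epsilon * epsilon) break;
    }
  }
  NumericMatrix uo(H, W), vo(H, W);
  std::copy(u.begin(), u.end(), uo.begin());
  std::copy(v.begin(), v.end(), vo.begin());
  return List::create(_["u"] = uo, _["v"] = vo);
}
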