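// Dense 2-D convolution and max-pooling kernels for the three-branch
// attention network. Activations are R arrays with dim (H, W, C, B),
// column-major; weights are (k*k*Cin) x Cout matrices whose row order is
// fixed by im2col below (input channel outermost, then kernel column,
// then kernel row). 'same' zero padding, stride 1, odd kernels only.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;

static void im2col_one(const double* x, int H, int W, int C, int k, mat& cols) {
  const int p = k / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        double* dst = cols.colptr(col);
        const int i0 = std::max(0, p - di);
        const int i1 = std::min(H, H + p - di);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          double* d2 = dst + (size_t)H * j;
          if (sj < 0 || sj >= W) {
            std::fill_n(d2, H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)H * sj;
          for (int i = 0; i < i0; ++i) d2[i] = 0.0;
          for (int i = i0; i < i1; ++i) d2[i] = src[i + di - p];
          for (int i = i1; i < H; ++i) d2[i] = 0.0;
        }
      }
    }
  }
}

static void col2im_add(const mat& dcols, int H, int W, int C, int k, double* dx) {
  const int p = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        const double* s = dcols.colptr(col);
        const int i0 = std::max(0, p - di);
        const int i1 = std::min(H, H + p - di);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          double* dsts = xc + (size_t)H * sj;
          const double* s2 = s + (size_t)H * j;
          for (int i = i0; i < i1; ++i) dsts[i + di - p] += s2[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix Wm, NumericVector b, int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int Cout = Wm.ncol();
  if (Wm.nrow() != k * k * C) stop("weight rows do not match k*k*Cin");
  mat Wmat(Wm.begin(), Wm.nrow(), Cout, false);
  arma::rowvec bias(b.begin(), Cout);
  NumericVector y((size_t)H * W * Cout * B);
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  if (k == 1) {
    // 1x1 conv: each batch slab is already an (H*W, C) matrix
    for (int bb = 0; bb < B; ++bb) {
      const mat xb(const_cast<double*>(x.begin()) + (size_t)H * W * C * bb,
                   H * W, C, false);
      mat yb(y.begin() + (size_t)H * W * Cout * bb, H * W, Cout, false, true);
      yb = xb * Wmat;
      yb.each_row() += bias;
    }
    return y;
  }
  mat cols(H * W, (size_t)k * k * C);
  for (int bb = 0; bb < B; ++bb) {
    im2col_one(x.begin() + (size_t)H * W * C * bb, H, W, C, k, cols);
    mat yb(y.begin() + (size_t)H * W * Cout * bb, H * W, Cout, false, true);
    yb = cols * Wmat;
    yb.each_row() += bias;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector dy, NumericMatrix Wm, int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int Cout = Wm.ncol();
  mat Wmat(Wm.begin(), Wm.nrow(), Cout, false);
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  NumericMatrix dW(Wm.nrow(), Cout);
  NumericVector db(Cout);
  mat dWa(dW.begin(), Wm.nrow(), Cout, false);
  arma::vec dba(db.begin(), Cout, false);
  if (k == 1) {
    for (int bb = 0; bb < B; ++bb) {
      const mat xb(const_cast<double*>(x.begin()) + (size_t)H * W * C * bb,
                   H * W, C, false);
      const mat dyb(const_cast<double*>(dy.begin()) + (size_t)H * W * Cout * bb,
                    H * W, Cout, false);
      mat dxb(dx.begin() + (size_t)H * W * C * bb, H * W, C, false, true);
      dWa += xb.t() * dyb;
      dba += arma::sum(dyb, 0).t();
      dxb = dyb * Wmat.t();
    }
    return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
  }
  mat cols(H * W, (size_t)k * k * C);
  for (int bb = 0; bb < B; ++bb) {
    im2col_one(x.begin() + (size_t)H * W * C * bb, H, W, C, k, cols);
    const mat dyb(const_cast<double*>(dy.begin()) + (size_t)H * W * Cout * bb,
                  H * W, Cout, false);
    dWa += cols.t() * dyb;
    dba += arma::sum(dyb, 0).t();
    mat dcols = dyb * Wmat.t();
    col2im_add(dcols, H, W, C, k, dx.begin() + (size_t)H * W * C * bb);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2. idx stores, per output element, the 0-based
// linear index of the winning element within its (H, W) input plane.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  IntegerVector idx((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  size_t o = 0;
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + (size_t)H * W * (c + (size_t)C * bb);
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = -1e300; int bi = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const int ii = 2 * i + di, jj = 2 * j + dj;
              const double v = plane[ii + (size_t)H * jj];
              if (v > best) { best = v; bi = ii + H * jj; }
            }
          }
          y[o] = best; idx[o] = bi; ++o;
        }
      }
    }
  }
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector d = dy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], B = d[3];
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  size_t o = 0;
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < C; ++c) {
      double* plane = dx.begin() + (size_t)H * W * (c + (size_t)C * bb);
      const size_t n = (size_t)Ho * Wo;
      for (size_t q = 0; q < n; ++q, ++o) plane[idx[o]] += dy[o];
    }
  }
  return dx;
}

// 3x3 max pooling, stride 1, 'same' padding (pad value -inf).
// [[Rcpp::export]]
List maxpool3s1_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  NumericVector y((size_t)H * W * C * B);
  IntegerVector idx((size_t)H * W * C * B);
  y.attr("dim") = IntegerVector::create(H, W, C, B);
  idx.attr("dim") = IntegerVector::create(H, W, C, B);
  size_t o = 0;
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + (size_t)H * W * (c + (size_t)C * bb);
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          double best = -1e300; int bi = 0;
          for (int dj = -1; dj <= 1; ++dj) {
            const int jj = j + dj;
            if (jj < 0 || jj >= W) continue;
            for (int di = -1; di <= 1; ++di) {
              const int ii = i + di;
              if (ii < 0 || ii >= H) continue;
              const double v = plane[ii + (size_t)H * jj];
              if (v > best) { best = v; bi = ii + H * jj; }
            }
          }
          y[o] = best; idx[o] = bi; ++o;
        }
      }
    }
  }
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3s1_bwd(NumericVector dy, IntegerVector idx) {
  IntegerVector d = dy.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  size_t o = 0;
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < C; ++c) {
      double* plane = dx.begin() + (size_t)H * W * (c + (size_t)C * bb);
      const size_t n = (size_t)H * W;
      for (size_t q = 0; q < n; ++q, ++o) plane[idx[o]] += dy[o];
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xi = x.begin();
  double* yo = y.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) yo[i] = xi[i] > 0 ? xi[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector dout, NumericVector out) {
  NumericVector dx(dout.size());
  dx.attr("dim") = dout.attr("dim");
  const double* d = dout.begin();
  const double* o = out.begin();
  double* r = dx.begin();
  const size_t n = dout.size();
  for (size_t i = 0; i < n; ++i) r[i] = o[i] > 0 ? d[i] : 0;
  return dx;
}
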