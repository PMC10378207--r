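// Supporting kernels for the attention modules: channel concat/split,
// channel-wise broadcasts and reductions, and the SAM mean/max pooling
// over channels with its backward scatter.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector concat_channels(List xs) {
  const int n = xs.size();
  std::vector<NumericVector> v;
  int Ct = 0, H = 0, W = 0, B = 0;
  for (int i = 0; i < n; ++i) {
    NumericVector x = xs[i];
    IntegerVector d = x.attr("dim");
    if (i == 0) { H = d[0]; W = d[1]; B = d[3]; }
    Ct += d[2];
    v.push_back(x);
  }
  NumericVector y((size_t)H * W * Ct * B);
  y.attr("dim") = IntegerVector::create(H, W, Ct, B);
  const size_t plane = (size_t)H * W;
  for (int bb = 0; bb < B; ++bb) {
    double* dst = y.begin() + plane * Ct * bb;
    for (int i = 0; i < n; ++i) {
      IntegerVector d = v[i].attr("dim");
      const size_t blk = plane * d[2];
      std::copy(v[i].begin() + blk * bb, v[i].begin() + blk * (bb + 1), dst);
      dst += blk;
    }
  }
  return y;
}

// [[Rcpp::export]]
List split_channels(NumericVector x, IntegerVector sizes) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], B = d[3];
  const size_t plane = (size_t)H * W;
  const int Ct = d[2];
  List out(sizes.size());
  int at = 0;
  for (int i = 0; i < sizes.size(); ++i) {
    const int C = sizes[i];
    NumericVector yi(plane * C * B);
    yi.attr("dim") = IntegerVector::create(H, W, C, B);
    for (int bb = 0; bb < B; ++bb)
      std::copy(x.begin() + plane * ((size_t)Ct * bb + at),
                x.begin() + plane * ((size_t)Ct * bb + at + C),
                yi.begin() + plane * (size_t)C * bb);
    at += C;
    out[i] = yi;
  }
  return out;
}

// channel-wise mean and max over C: returns (H, W, 2, B) plus argmax
// channel indices (1-based, HW x B)
// [[Rcpp::export]]
List chan_mean_max(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(plane * 2 * B);
  y.attr("dim") = IntegerVector::create(H, W, 2, B);
  IntegerMatrix amx(plane, B);
  for (int bb = 0; bb < B; ++bb) {
    const double* xb = x.begin() + plane * (size_t)C * bb;
    double* mn = y.begin() + plane * 2 * (size_t)bb;
    double* mx = mn + plane;
    for (size_t q = 0; q < plane; ++q) {
      double s = 0, best = -1e300; int bi = 0;
      for (int c = 0; c < C; ++c) {
        const double val = xb[q + plane * c];
        s += val;
        if (val > best) { best = val; bi = c; }
      }
      mn[q] = s / C; mx[q] = best; amx(q, bb) = bi + 1;
    }
  }
  return List::create(_["mnmx"] = y, _["amx"] = amx);
}

// backward of chan_mean_max: spread dmean / C to all channels, scatter dmax
// to the argmax channel
// [[Rcpp::export]]
NumericVector chan_mean_max_bwd(NumericVector dmnmx, IntegerMatrix amx,
                                int C) {
  IntegerVector d = dmnmx.attr("dim");
  const int H = d[0], W = d[1], B = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector dx(plane * (size_t)C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  for (int bb = 0; bb < B; ++bb) {
    const double* dmn = dmnmx.begin() + plane * 2 * (size_t)bb;
    const double* dmx = dmn + plane;
    double* dxb = dx.begin() + plane * (size_t)C * bb;
    for (size_t q = 0; q < plane; ++q) {
      const double dm = dmn[q] / C;
      for (int c = 0; c < C; ++c) dxb[q + plane * c] = dm;
      dxb[q + plane * (size_t)(amx(q, bb) - 1)] += dmx[q];
    }
  }
  return dx;
}

// y[i,j,c,b] = x[i,j,c,b] * a[c,b] (+ optional residual add of x)
// [[Rcpp::export]]
NumericVector bcast_mul(NumericVector x, NumericMatrix a, bool plusOne = false) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      const double f = plusOne ? 1.0 + a(c, bb) : a(c, bb);
      const double* xi = x.begin() + plane * (c + (size_t)C * bb);
      double* yo = y.begin() + plane * (c + (size_t)C * bb);
      for (size_t q = 0; q < plane; ++q) yo[q] = xi[q] * f;
    }
  return y;
}

// s[c,b] = sum_{i,j} x[i,j,c,b] * w[i,j,c,b] (w optional)
// [[Rcpp::export]]
NumericMatrix chan_spatial_dot(NumericVector x, NumericVector w) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const size_t plane = (size_t)H * W;
  NumericMatrix s(C, B);
  const bool hasW = w.size() == x.size();
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      const double* xi = x.begin() + plane * (c + (size_t)C * bb);
      double acc = 0;
      if (hasW) {
        const double* wi = w.begin() + plane * (c + (size_t)C * bb);
        for (size_t q = 0; q < plane; ++q) acc += xi[q] * wi[q];
      } else {
        for (size_t q = 0; q < plane; ++q) acc += xi[q];
      }
      s(c, bb) = acc;
    }
  return s;
}

// y[i,j,c,b] = a[c,b] (broadcast a channel vector over space)
// [[Rcpp::export]]
NumericVector bcast_channel(NumericMatrix a, int H, int W) {
  const int C = a.nrow(), B = a.ncol();
  const size_t plane = (size_t)H * W;
  NumericVector y(plane * (size_t)C * B);
  y.attr("dim") = IntegerVector::create(H, W, C, B);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c)
      std::fill_n(y.begin() + plane * (c + (size_t)C * bb), plane, a(c, bb));
  return y;
}

// spatial gate: y = x * attn (attn is (H, W, 1, B), broadcast over C)
// [[Rcpp::export]]
NumericVector spatial_gate(NumericVector x, NumericVector attn) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int bb = 0; bb < B; ++bb) {
    const double* ab = attn.begin() + plane * bb;
    for (int c = 0; c < C; ++c) {
      const double* xi = x.begin() + plane * (c + (size_t)C * bb);
      double* yo = y.begin() + plane * (c + (size_t)C * bb);
      for (size_t q = 0; q < plane; ++q) yo[q] = xi[q] * ab[q];
    }
  }
  return y;
}

// dattn[i,j,1,b] = sum_c dout[i,j,c,b] * x[i,j,c,b]
// [[Rcpp::export]]
NumericVector spatial_gate_bwd_attn(NumericVector dout, NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(plane * (size_t)B);
  y.attr("dim") = IntegerVector::create(H, W, 1, B);
  for (int bb = 0; bb < B; ++bb) {
    double* yo = y.begin() + plane * bb;
    std::fill_n(yo, plane, 0.0);
    for (int c = 0; c < C; ++c) {
      const double* di = dout.begin() + plane * (c + (size_t)C * bb);
      const double* xi = x.begin() + plane * (c + (size_t)C * bb);
      for (size_t q = 0; q < plane; ++q) yo[q] += di[q] * xi[q];
    }
  }
  return y;
}
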