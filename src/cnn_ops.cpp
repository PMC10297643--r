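// Low-level CNN kernels: im2col convolution over BLAS gemm, max-pooling with
// argmax bookkeeping, and bilinear resampling, each with its adjoint for
// backpropagation. Tensors are R arrays in (H, W, C, N) column-major layout;
// convolution weights are (kh, kw, Cin, Cout). All arithmetic is double.
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int conv_out(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix for one sample: (Ho*Wo) x (kh*kw*Cin), column
// q = i + kh*(j + kw*ci) holds input pixel (ho*s - pad + i, wo*s - pad + j)
// of channel ci, rows ordered with ho fastest. Zero padding.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  col.zeros();
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        double* dst = col.colptr((size_t)i + kh * ((size_t)j + kw * ci));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (size_t)wi * H;
          double* drow = dst + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            if (hi >= 0 && hi < H) drow[ho] = xcol[hi];
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add columns back into the input gradient.
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (size_t)ci * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const double* src = col.colptr((size_t)i + kh * ((size_t)j + kw * ci));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          const double* srow = src + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            if (hi >= 0 && hi < H) xcol[hi] += srow[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but weights expect %d", C, Cin);
  int Ho = conv_out(H, kh, stride, pad), Wo = conv_out(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  NumericVector y(Ho * (R_xlen_t)Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(Ho * (size_t)Wo, (size_t)kh * kw * C);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat out(y.begin() + (size_t)n * Ho * Wo * Cout, Ho * (size_t)Wo, Cout, false, true);
    out = col * Wm;
    if (b.size() > 0) out.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout, false, true);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx(need_dx ? x.size() : 0), dw(w.size()), db(Cout);
  if (need_dx) dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat col(Ho * (size_t)Wo, (size_t)kh * kw * C);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Cout, false, true);
  arma::mat dWm(dw.begin(), (size_t)kh * kw * C, Cout, false, true);
  arma::rowvec dB(db.begin(), Cout, false, true);
  arma::mat dcol;
  for (int n = 0; n < N; ++n) {
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                 Ho * (size_t)Wo, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    dWm += col.t() * dY;
    dB += arma::sum(dY, 0);
    if (need_dx) {
      dcol = dY * Wm.t();
      col2im(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
             dx.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpoolForward")]]
List maxpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = conv_out(H, k, stride, pad), Wo = conv_out(W, k, stride, pad);
  NumericVector y(Ho * (R_xlen_t)Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      size_t base = ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; int bi = -1;
          for (int j = 0; j < k; ++j) {
            int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              double v = xc[(size_t)wi * H + hi];
              if (v > best) { best = v; bi = wi * H + hi; }
            }
          }
          size_t o = base + (size_t)wo * Ho + ho;
          y[o] = best;
          idx[o] = bi;  // 0-based index within the (H, W) plane
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpoolBackward")]]
NumericVector maxpool_backward(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + ((size_t)n * C + c) * H * W;
      size_t base = ((size_t)n * C + c) * Ho * Wo;
      for (size_t o = 0; o < (size_t)Ho * Wo; ++o)
        if (idx[base + o] >= 0) xc[idx[base + o]] += dy[base + o];
    }
  return dx;
}

// Bilinear resize with half-pixel centers and edge clamping; preserves
// constants exactly and is a fixed linear map, so the backward pass is its
// transpose (scatter-add of the same weights).
static void bilin_coeff(int out, int in, std::vector<int>& i0,
                        std::vector<int>& i1, std::vector<double>& w1) {
  double scale = (double)in / out;
  i0.resize(out); i1.resize(out); w1.resize(out);
  for (int o = 0; o < out; ++o) {
    double s = (o + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > in - 1) s = in - 1;
    int a = (int)std::floor(s);
    int b = a + 1 < in ? a + 1 : in - 1;
    i0[o] = a; i1[o] = b; w1[o] = s - a;
  }
}

// [[Rcpp::export(name = ".resizeBilinear")]]
NumericVector resize_bilinear(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (Ho < 1 || Wo < 1) stop("resize: target size must be positive");
  std::vector<int> h0, h1, w0, w1v; std::vector<double> hw, ww;
  bilin_coeff(Ho, H, h0, h1, hw);
  bilin_coeff(Wo, W, w0, w1v, ww);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* xc = x.begin() + p * H * W;
    double* yc = y.begin() + p * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const double* cL = xc + (size_t)w0[wo] * H;
      const double* cR = xc + (size_t)w1v[wo] * H;
      double aw = ww[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        double top = cL[h0[ho]] * (1 - aw) + cR[h0[ho]] * aw;
        double bot = cL[h1[ho]] * (1 - aw) + cR[h1[ho]] * aw;
        yc[(size_t)wo * Ho + ho] = top * (1 - hw[ho]) + bot * hw[ho];
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".resizeBilinearBackward")]]
NumericVector resize_bilinear_backward(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  std::vector<int> h0, h1, w0, w1v; std::vector<double> hw, ww;
  bilin_coeff(Ho, H, h0, h1, hw);
  bilin_coeff(Wo, W, w0, w1v, ww);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* yc = dy.begin() + p * Ho * Wo;
    double* xc = dx.begin() + p * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      double aw = ww[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        double g = yc[(size_t)wo * Ho + ho], bw = hw[ho];
        xc[(size_t)w0[wo] * H + h0[ho]] += g * (1 - aw) * (1 - bw);
        xc[(size_t)w1v[wo] * H + h0[ho]] += g * aw * (1 - bw);
        xc[(size_t)w0[wo] * H + h1[ho]] += g * (1 - aw) * bw;
        xc[(size_t)w1v[wo] * H + h1[ho]] += g * aw * bw;
      }
    }
  }
  return dx;
}

// ---- fused elementwise/channel kernels (hot paths of batch norm & ReLU) ----

// y = x * s[c] + t[c]; t may be empty.
// [[Rcpp::export(name = ".channelAffine")]]
NumericVector channel_affine(NumericVector x, NumericVector s, NumericVector t) {
  IntegerVector xd = x.attr("dim");
  size_t hw = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  bool shift = t.size() > 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)n * C + c) * hw;
      double* yp = y.begin() + ((size_t)n * C + c) * hw;
      double sc = s[c], tc = shift ? t[c] : 0.0;
      for (size_t i = 0; i < hw; ++i) yp[i] = xp[i] * sc + tc;
    }
  return y;
}

// per-channel sum of x (b empty) or of x*b.
// [[Rcpp::export(name = ".channelDot")]]
NumericVector channel_dot(NumericVector x, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  size_t hw = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector out(C);
  bool prod = b.size() > 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)n * C + c) * hw;
      const double* bp = prod ? b.begin() + ((size_t)n * C + c) * hw : nullptr;
      double acc = 0;
      if (prod) for (size_t i = 0; i < hw; ++i) acc += xp[i] * bp[i];
      else for (size_t i = 0; i < hw; ++i) acc += xp[i];
      out[c] += acc;
    }
  return out;
}

// dx = (dy - a[c] - xhat * b[c]) * g[c]   (batch-norm input gradient)
// [[Rcpp::export(name = ".bnBackwardKernel")]]
NumericVector bn_backward_kernel(NumericVector dy, NumericVector xhat,
                                 NumericVector a, NumericVector b,
                                 NumericVector g) {
  IntegerVector xd = dy.attr("dim");
  size_t hw = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector dx(dy.size());
  dx.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = ((size_t)n * C + c) * hw;
      const double* dp = dy.begin() + off;
      const double* xp = xhat.begin() + off;
      double* op = dx.begin() + off;
      double ac = a[c], bc = b[c], gc = g[c];
      for (size_t i = 0; i < hw; ++i) op[i] = (dp[i] - ac - xp[i] * bc) * gc;
    }
  return dx;
}

// [[Rcpp::export(name = ".reluFwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".reluBwd")]]
NumericVector relu_bwd(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0.0;
  return dx;
}
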