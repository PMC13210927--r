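// Hot numerical kernels for the segmentation network: grouped/dilated 2-D
// convolution via im2col + BLAS, and bilinear resize (both with backward
// passes, so they can serve as differentiable layers).
//
// Tensor layout throughout: R arrays of dim c(H, W, C, N), column-major,
// i.e. element (h, w, c, n) sits at h + H*(w + W*(c + C*n)).
// Convolution weights: dim c(kh, kw, Cin_per_group, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int conv_out_dim(int in, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// Fill a K x (Ho*Wo) im2col matrix for one (sample, group) slab.
// K = kh*kw*Cg, rows ordered i + kh*(j + kw*ci)  (matches weight layout).
static void im2col(const double* x, int H, int W, int Cg, int c0,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, int CHW_offset, arma::mat& col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int out_idx = ho + Ho * wo;
      double* dst = col.colptr(out_idx);
      for (int ci = 0; ci < Cg; ++ci) {
        const double* xc = x + CHW_offset + (size_t)(c0 + ci) * H * W;
        for (int j = 0; j < kw; ++j) {
          int w_in = wo * stride - pad + j * dil;
          for (int i = 0; i < kh; ++i) {
            int h_in = ho * stride - pad + i * dil;
            double v = 0.0;
            if (h_in >= 0 && h_in < H && w_in >= 0 && w_in < W)
              v = xc[h_in + (size_t)H * w_in];
            dst[i + kh * (j + kw * ci)] = v;
          }
        }
      }
    }
  }
}

// Scatter-add a col matrix back into the input gradient (transpose of im2col).
static void col2im(double* gx, int H, int W, int Cg, int c0,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, int CHW_offset, const arma::mat& col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int out_idx = ho + Ho * wo;
      const double* src = col.colptr(out_idx);
      for (int ci = 0; ci < Cg; ++ci) {
        double* xc = gx + CHW_offset + (size_t)(c0 + ci) * H * W;
        for (int j = 0; j < kw; ++j) {
          int w_in = wo * stride - pad + j * dil;
          if (w_in < 0 || w_in >= W) continue;
          for (int i = 0; i < kh; ++i) {
            int h_in = ho * stride - pad + i * dil;
            if (h_in < 0 || h_in >= H) continue;
            xc[h_in + (size_t)H * w_in] += src[i + kh * (j + kw * ci)];
          }
        }
      }
    }
  }
}

// Depthwise fast path (one input channel per group, one output per group).
static void depthwise_forward(const double* x, const double* w,
                              const double* bias, bool has_bias, int H, int W,
                              int C, int N, int kh, int kw, int stride,
                              int pad, int dil, int Ho, int Wo, double* out) {
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w + (size_t)kh * kw * c;
      double b = has_bias ? bias[c] : 0.0;
      double* oc = out + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = b;
          for (int j = 0; j < kw; ++j) {
            int wi = wo * stride - pad + j * dil;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              int hi = ho * stride - pad + i * dil;
              if (hi < 0 || hi >= H) continue;
              acc += xc[hi + (size_t)H * wi] * wc[i + kh * j];
            }
          }
          oc[ho + (size_t)Ho * wo] = acc;
        }
      }
    }
  }
}

static void depthwise_backward(const double* x, const double* w,
                               const double* gy, int H, int W, int C, int N,
                               int kh, int kw, int stride, int pad, int dil,
                               int Ho, int Wo, double* gx, double* gw,
                               double* gb, bool has_bias) {
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w + (size_t)kh * kw * c;
      const double* gyc = gy + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* gxc = gx + (size_t)H * W * (c + (size_t)C * n);
      double* gwc = gw + (size_t)kh * kw * c;
      double gbacc = 0.0;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double g = gyc[ho + (size_t)Ho * wo];
          if (has_bias) gbacc += g;
          for (int j = 0; j < kw; ++j) {
            int wi = wo * stride - pad + j * dil;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              int hi = ho * stride - pad + i * dil;
              if (hi < 0 || hi >= H) continue;
              gxc[hi + (size_t)H * wi] += g * wc[i + kh * j];
              gwc[i + kh * j] += g * xc[hi + (size_t)H * wi];
            }
          }
        }
      }
      if (has_bias) gb[c] += gbacc;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector bias, IntegerVector xdim,
                                 IntegerVector wdim, int stride, int pad,
                                 int dil, int groups) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int kh = wdim[0], kw = wdim[1], Cg = wdim[2], Cout = wdim[3];
  if (C != Cg * groups) stop("conv2d: input channels inconsistent with groups");
  if (Cout % groups != 0) stop("conv2d: output channels not divisible by groups");
  int Cog = Cout / groups;
  int Ho = conv_out_dim(H, kh, stride, pad, dil);
  int Wo = conv_out_dim(W, kw, stride, pad, dil);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  int K = kh * kw * Cg;

  NumericVector out((size_t)Ho * Wo * Cout * N);
  if (Cg == 1 && Cout == C) {
    depthwise_forward(x.begin(), w.begin(), bias.begin(), bias.size() > 0,
                      H, W, C, N, kh, kw, stride, pad, dil, Ho, Wo,
                      out.begin());
    out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
    return out;
  }
  arma::mat col(K, (size_t)Ho * Wo);
  // weight views per group: (Cog x K)
  const double* wp = w.begin();
  bool has_bias = bias.size() > 0;

  for (int n = 0; n < N; ++n) {
    size_t xoff = (size_t)H * W * C * n;
    size_t ooff = (size_t)Ho * Wo * Cout * n;
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, Cg, g * Cg, kh, kw, stride, pad, dil, Ho, Wo,
             (int)xoff, col);
      // Build Wg as K x Cog (weights for out-channels g*Cog .. ) then out = Wg' * col
      arma::mat Wg(K, Cog);
      for (int co = 0; co < Cog; ++co)
        std::copy(wp + (size_t)K * (g * Cog + co),
                  wp + (size_t)K * (g * Cog + co + 1), Wg.colptr(co));
      arma::mat O = Wg.t() * col;  // Cog x (Ho*Wo)
      for (int co = 0; co < Cog; ++co) {
        double b = has_bias ? bias[g * Cog + co] : 0.0;
        double* dst = out.begin() + ooff + (size_t)Ho * Wo * (g * Cog + co);
        const arma::mat Orow = O.row(co);
        for (size_t p = 0; p < (size_t)Ho * Wo; ++p) dst[p] = Orow(p) + b;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         IntegerVector xdim, IntegerVector wdim, int stride,
                         int pad, int dil, int groups, bool has_bias) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int kh = wdim[0], kw = wdim[1], Cg = wdim[2], Cout = wdim[3];
  int Cog = Cout / groups;
  int Ho = conv_out_dim(H, kh, stride, pad, dil);
  int Wo = conv_out_dim(W, kw, stride, pad, dil);
  int K = kh * kw * Cg;
  size_t HoWo = (size_t)Ho * Wo;

  NumericVector gx((size_t)H * W * C * N);
  NumericVector gw((size_t)kh * kw * Cg * Cout);
  NumericVector gb(has_bias ? Cout : 0);

  if (Cg == 1 && Cout == C) {
    depthwise_backward(x.begin(), w.begin(), gy.begin(), H, W, C, N, kh, kw,
                       stride, pad, dil, Ho, Wo, gx.begin(), gw.begin(),
                       gb.begin(), has_bias);
    gx.attr("dim") = xdim;
    gw.attr("dim") = wdim;
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }

  arma::mat col(K, HoWo);
  const double* wp = w.begin();

  for (int n = 0; n < N; ++n) {
    size_t xoff = (size_t)H * W * C * n;
    size_t ooff = HoWo * Cout * n;
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, Cg, g * Cg, kh, kw, stride, pad, dil, Ho, Wo,
             (int)xoff, col);
      // Gy slab for this group: Cog x HoWo
      arma::mat Gy(Cog, HoWo);
      for (int co = 0; co < Cog; ++co) {
        const double* src = gy.begin() + ooff + HoWo * (g * Cog + co);
        for (size_t p = 0; p < HoWo; ++p) Gy(co, p) = src[p];
        if (has_bias) {
          double s = 0.0;
          for (size_t p = 0; p < HoWo; ++p) s += src[p];
          gb[g * Cog + co] += s;
        }
      }
      // dW (K x Cog) += col * Gy'
      arma::mat dW = col * Gy.t();
      for (int co = 0; co < Cog; ++co) {
        double* dst = gw.begin() + (size_t)K * (g * Cog + co);
        for (int k = 0; k < K; ++k) dst[k] += dW(k, co);
      }
      // dcol (K x HoWo) = Wg * Gy
      arma::mat Wg(K, Cog);
      for (int co = 0; co < Cog; ++co)
        std::copy(wp + (size_t)K * (g * Cog + co),
                  wp + (size_t)K * (g * Cog + co + 1), Wg.colptr(co));
      arma::mat dcol = Wg * Gy;
      col2im(gx.begin(), H, W, Cg, g * Cg, kh, kw, stride, pad, dil, Ho, Wo,
             (int)xoff, dcol);
    }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Bilinear resize with half-pixel-center sampling (the convention used when
// resizing without corner alignment). Border samples are clamped.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, IntegerVector xdim,
                                  int Ho, int Wo) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector out((size_t)Ho * Wo * C * N);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (int i = 0; i < Ho; ++i) {
    double src = (i + 0.5) * sh - 0.5;
    if (src < 0) src = 0;
    if (src > H - 1) src = H - 1;
    h0[i] = (int)std::floor(src);
    h1[i] = std::min(h0[i] + 1, H - 1);
    fh[i] = src - h0[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double src = (j + 0.5) * sw - 0.5;
    if (src < 0) src = 0;
    if (src > W - 1) src = W - 1;
    w0[j] = (int)std::floor(src);
    w1[j] = std::min(w0[j] + 1, W - 1);
    fw[j] = src - w0[j];
  }
  for (int cn = 0; cn < C * N; ++cn) {
    const double* src = x.begin() + (size_t)H * W * cn;
    double* dst = out.begin() + (size_t)Ho * Wo * cn;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double a = src[h0[i] + (size_t)H * w0[j]];
        double b = src[h1[i] + (size_t)H * w0[j]];
        double c = src[h0[i] + (size_t)H * w1[j]];
        double d = src[h1[i] + (size_t)H * w1[j]];
        double top = a + (b - a) * fh[i];
        double bot = c + (d - c) * fh[i];
        dst[i + (size_t)Ho * j] = top + (bot - top) * fw[j];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// Transpose of cpp_resize_bilinear: scatter output gradients to input cells.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_backward(NumericVector gy, IntegerVector ydim,
                                           int H, int W) {
  int Ho = ydim[0], Wo = ydim[1], C = ydim[2], N = ydim[3];
  NumericVector gx((size_t)H * W * C * N);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (int i = 0; i < Ho; ++i) {
    double src = (i + 0.5) * sh - 0.5;
    if (src < 0) src = 0;
    if (src > H - 1) src = H - 1;
    h0[i] = (int)std::floor(src);
    h1[i] = std::min(h0[i] + 1, H - 1);
    fh[i] = src - h0[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double src = (j + 0.5) * sw - 0.5;
    if (src < 0) src = 0;
    if (src > W - 1) src = W - 1;
    w0[j] = (int)std::floor(src);
    w1[j] = std::min(w0[j] + 1, W - 1);
    fw[j] = src - w0[j];
  }
  for (int cn = 0; cn < C * N; ++cn) {
    double* dst = gx.begin() + (size_t)H * W * cn;
    const double* src = gy.begin() + (size_t)Ho * Wo * cn;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double g = src[i + (size_t)Ho * j];
        double a = (1 - fh[i]) * (1 - fw[j]);
        double b = fh[i] * (1 - fw[j]);
        double c = (1 - fh[i]) * fw[j];
        double d = fh[i] * fw[j];
        dst[h0[i] + (size_t)H * w0[j]] += g * a;
        dst[h1[i] + (size_t)H * w0[j]] += g * b;
        dst[h0[i] + (size_t)H * w1[j]] += g * c;
        dst[h1[i] + (size_t)H * w1[j]] += g * d;
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}
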