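// Convolution kernels for the network engine.
//
// Tensor layout follows R's column-major array convention:
//   activations  x : dim (H, W, C, N)
//   conv weights w : dim (kh, kw, Cin, Cout)
//   depthwise  w   : dim (kh, kw, C)
// Standard convolutions go through im2col + BLAS gemm; depthwise
// convolutions (one filter per channel) use direct loops, where im2col
// buys nothing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static NumericVector alloc4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Fill the im2col patch matrix M ((Ho*Wo) x (kh*kw*Cin)) for sample n.
// pad_mode 0: zero padding; 1: replicate (edge) padding.
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static void im2col(const double* x, int H, int W, int Cin, long sample_off,
                   int kh, int kw, int stride, int pad, int pad_mode,
                   int Ho, int Wo, arma::mat& M) {
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + sample_off + (long)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        double* Mcol = M.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          double* Mc = Mcol + (long)Ho * wo;
          if (wi < 0 || wi >= W) {
            if (pad_mode == 0) {
              std::fill(Mc, Mc + Ho, 0.0);
              continue;
            }
            wi = clampi(wi, 0, W - 1);
          }
          const double* xcol = xc + (long)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H)
              Mc[ho] = pad_mode == 0 ? 0.0 : xcol[clampi(hi, 0, H - 1)];
            else
              Mc[ho] = xcol[hi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            NumericVector bias, int stride, int pad,
                            int pad_mode) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: input has %d channels but weights expect %d", Cin, wd[2]);
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: image smaller than kernel support");

  const arma::mat Wm(const_cast<double*>(w.begin()), (long)kh * kw * Cin, Cout, false, true);
  NumericVector y = alloc4d(Ho, Wo, Cout, N);
  arma::mat M((long)Ho * Wo, (long)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, Cin, (long)H * W * Cin * n, kh, kw, stride, pad, pad_mode, Ho, Wo, M);
    arma::mat Y(y.begin() + (long)Ho * Wo * Cout * n, (long)Ho * Wo, Cout, false, true);
    Y = M * Wm;
    if (bias.size() == Cout)
      for (int c = 0; c < Cout; ++c) Y.col(c) += bias[c];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad, int pad_mode, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);

  const arma::mat Wm(const_cast<double*>(w.begin()), (long)kh * kw * Cin, Cout, false, true);
  NumericVector gx = alloc4d(H, W, Cin, N);
  NumericVector gw = alloc4d(kh, kw, Cin, Cout);
  NumericVector gb(has_bias ? Cout : 0);
  arma::mat Gw(gw.begin(), (long)kh * kw * Cin, Cout, false, true);

  arma::mat M((long)Ho * Wo, (long)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    const long xoff = (long)H * W * Cin * n;
    im2col(x.begin(), H, W, Cin, xoff, kh, kw, stride, pad, pad_mode, Ho, Wo, M);
    const arma::mat G(const_cast<double*>(gy.begin()) + (long)Ho * Wo * Cout * n,
                      (long)Ho * Wo, Cout, false, true);
    Gw += M.t() * G;
    if (has_bias)
      for (int c = 0; c < Cout; ++c) gb[c] += arma::accu(G.col(c));
    // col2im scatter-add of G * Wm^T
    arma::mat Gcol = G * Wm.t(); // (Ho*Wo) x (kh*kw*Cin)
    double* gxn = gx.begin() + xoff;
    for (int c = 0; c < Cin; ++c) {
      double* gxc = gxn + (long)H * W * c;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const double* Gc = Gcol.colptr(ki + kh * (kj + kw * c));
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) {
              if (pad_mode == 0) continue;
              wi = clampi(wi, 0, W - 1);
            }
            const double* Gcw = Gc + (long)Ho * wo;
            double* gcol = gxc + (long)H * wi;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) {
                if (pad_mode == 0) continue;
                hi = clampi(hi, 0, H - 1);
              }
              gcol[hi] += Gcw[ho];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_dwconv2d_fw(NumericVector x, NumericVector w,
                              NumericVector bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("dwconv2d: channel mismatch (%d vs %d)", C, wd[2]);
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("dwconv2d: image smaller than kernel support");

  NumericVector y = alloc4d(Ho, Wo, C, N);
  const bool hb = bias.size() == C;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (long)H * W * (c + (long)C * n);
      const double* wc = w.begin() + (long)kh * kw * c;
      double* yc = y.begin() + (long)Ho * Wo * (c + (long)C * n);
      const double b0 = hb ? bias[c] : 0.0;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = b0;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi >= 0 && hi < H) acc += wc[ki + kh * kj] * xc[hi + (long)H * wi];
            }
          }
          yc[ho + (long)Ho * wo] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                     int stride, int pad, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);

  NumericVector gx = alloc4d(H, W, C, N);
  NumericVector gw(Dimension(kh, kw, C));
  NumericVector gb(has_bias ? C : 0);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (long)H * W * (c + (long)C * n);
      const double* wc = w.begin() + (long)kh * kw * c;
      const double* gc = gy.begin() + (long)Ho * Wo * (c + (long)C * n);
      double* gxc = gx.begin() + (long)H * W * (c + (long)C * n);
      double* gwc = gw.begin() + (long)kh * kw * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gc[ho + (long)Ho * wo];
          if (has_bias) gb[c] += g;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              gwc[ki + kh * kj] += g * xc[hi + (long)H * wi];
              gxc[hi + (long)H * wi] += g * wc[ki + kh * kj];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 8-connected component labeling by breadth-first flood fill.
// Returns an integer matrix: 0 = background, components numbered from 1
// in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int> > queue;
  const int dh8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dw8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dh4[] = {-1, 1, 0, 0};
  const int dw4[] = {0, 0, -1, 1};
  const int* dh = connectivity == 8 ? dh8 : dh4;
  const int* dw = connectivity == 8 ? dw8 : dw4;
  int next = 0;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w) || lab(h, w) != 0) continue;
      ++next;
      lab(h, w) = next;
      queue.clear();
      queue.push_back(std::make_pair(h, w));
      while (!queue.empty()) {
        std::pair<int, int> p = queue.back();
        queue.pop_back();
        for (int k = 0; k < connectivity; ++k) {
          const int nh = p.first + dh[k], nw = p.second + dw[k];
          if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
          if (mask(nh, nw) && lab(nh, nw) == 0) {
            lab(nh, nw) = next;
            queue.push_back(std::make_pair(nh, nw));
          }
        }
      }
    }
  }
  return lab;
}
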