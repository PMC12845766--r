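// Low-level tensor kernels for the segmentation network.
//
// Tensor layout follows R's column-major arrays:
//   activations  x : (H, W, C, B)
//   conv weights w : (kh, kw, Cin, Cout)
//   tconv weights  : (2, 2, Cin, Cout)
// Stride-1 "same" convolutions are evaluated as im2col + GEMM so they run
// through BLAS; the 2x2/stride-2 pooling and transposed convolution are
// cheap relative to the convolutions and use direct loops.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void dims4(const NumericVector &x, int &d1, int &d2, int &d3,
                         int &d4) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  d1 = d[0]; d2 = d[1]; d3 = d[2]; d4 = d[3];
}

static inline NumericVector num4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector int4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Fill the im2col matrix for one sample: rows = output pixels (H*W, pixel
// index i + H*j), cols = kernel elements (m + kh*(n + kw*c)), zero padding.
static void im2col(const double *x, int H, int W, int C, int kh, int kw,
                   int pad, arma::mat &cols) {
  const int npix = H * W;
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * H * W;
    for (int n = 0; n < kw; ++n) {
      for (int m = 0; m < kh; ++m) {
        const int col = m + kh * (n + kw * c);
        double *dst = cols.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int jj = j + n - pad;
          if (jj < 0 || jj >= W) continue;
          const double *src = xc + (size_t)jj * H;
          double *d = dst + (size_t)j * H;
          const int i0 = std::max(0, pad - m);
          const int i1 = std::min(H, H + pad - m);
          for (int i = i0; i < i1; ++i) d[i] = src[i + m - pad];
        }
      }
    }
  }
  (void)npix;
}

// Scatter-add the column form back into an (H, W, C) image (adjoint of
// im2col), used for input gradients.
static void col2im_add(const arma::mat &cols, int H, int W, int C, int kh,
                       int kw, int pad, double *gx) {
  for (int c = 0; c < C; ++c) {
    double *gc = gx + (size_t)c * H * W;
    for (int n = 0; n < kw; ++n) {
      for (int m = 0; m < kh; ++m) {
        const int col = m + kh * (n + kw * c);
        const double *src = cols.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int jj = j + n - pad;
          if (jj < 0 || jj >= W) continue;
          double *dstc = gc + (size_t)jj * H;
          const double *s = src + (size_t)j * H;
          const int i0 = std::max(0, pad - m);
          const int i1 = std::min(H, H + pad - m);
          for (int i = i0; i < i1; ++i) dstc[i + m - pad] += s[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int pad) {
  int H, W, C, B, kh, kw, Cin, Cout;
  dims4(x, H, W, C, B);
  dims4(w, kh, kw, Cin, Cout);
  if (Cin != C) stop("channel mismatch between input and kernel");
  const int npix = H * W, K = kh * kw * Cin;
  NumericVector y = num4(H, W, Cout, B);
  arma::mat Wm(const_cast<double *>(w.begin()), K, Cout, false, true);
  arma::mat cols(npix, K);
  for (int s = 0; s < B; ++s) {
    im2col(x.begin() + (size_t)s * npix * C, H, W, C, kh, kw, pad, cols);
    arma::mat Y(y.begin() + (size_t)s * npix * Cout, npix, Cout, false, true);
    Y = cols * Wm;
    for (int k = 0; k < Cout; ++k) Y.col(k) += b[k];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy, int pad) {
  int H, W, C, B, kh, kw, Cin, Cout;
  dims4(x, H, W, C, B);
  dims4(w, kh, kw, Cin, Cout);
  const int npix = H * W, K = kh * kw * Cin;
  NumericVector gx = num4(H, W, C, B);
  NumericVector gw = num4(kh, kw, Cin, Cout);
  NumericVector gb(Cout);
  arma::mat Wm(const_cast<double *>(w.begin()), K, Cout, false, true);
  arma::mat GW(gw.begin(), K, Cout, false, true);
  arma::vec GB(gb.begin(), Cout, false, true);
  arma::mat cols(npix, K);
  for (int s = 0; s < B; ++s) {
    im2col(x.begin() + (size_t)s * npix * C, H, W, C, kh, kw, pad, cols);
    arma::mat G(const_cast<double *>(gy.begin()) + (size_t)s * npix * Cout,
                npix, Cout, false, true);
    GW += cols.t() * G;
    GB += arma::sum(G, 0).t();
    arma::mat Gc = G * Wm.t();  // npix x K
    col2im_add(Gc, H, W, C, kh, kw, pad,
               gx.begin() + (size_t)s * npix * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling with stride 2. Returns pooled values plus the flat index
// (within the sample's (H, W, C) slab, 0-based) of each maximum for the
// backward scatter.
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  int H, W, C, B;
  dims4(x, H, W, C, B);
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = num4(Ho, Wo, C, B);
  IntegerVector idx = int4(Ho, Wo, C, B);
  const size_t slab = (size_t)H * W * C, oslab = (size_t)Ho * Wo * C;
  for (int s = 0; s < B; ++s) {
    const double *xs = x.begin() + s * slab;
    double *ys = y.begin() + s * oslab;
    int *is = idx.begin() + s * oslab;
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          const int base = 2 * i + H * (2 * j) + H * W * c;
          int best = base;
          double bv = xs[base];
          const int cand[3] = {base + 1, base + H, base + H + 1};
          for (int q = 0; q < 3; ++q)
            if (xs[cand[q]] > bv) { bv = xs[cand[q]]; best = cand[q]; }
          const size_t o = i + (size_t)Ho * j + (size_t)Ho * Wo * c;
          ys[o] = bv;
          is[o] = best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(IntegerVector idx, NumericVector gy, int H, int W) {
  int Ho, Wo, C, B;
  dims4(gy, Ho, Wo, C, B);
  NumericVector gx = num4(H, W, C, B);
  const size_t slab = (size_t)H * W * C, oslab = (size_t)Ho * Wo * C;
  for (int s = 0; s < B; ++s) {
    const int *is = idx.begin() + s * oslab;
    const double *gs = gy.begin() + s * oslab;
    double *go = gx.begin() + s * slab;
    for (size_t o = 0; o < oslab; ++o) go[is[o]] += gs[o];
  }
  return gx;
}

// Transposed convolution, 2x2 kernel, stride 2 (exactly doubles H and W):
// y[2i+m, 2j+n, co] = sum_ci x[i, j, ci] * w[m, n, ci, co] + b[co].
// [[Rcpp::export(name = ".tconv2_fw")]]
NumericVector tconv2_fw(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, Cin, B, kh, kw, wCin, Cout;
  dims4(x, H, W, Cin, B);
  dims4(w, kh, kw, wCin, Cout);
  if (kh != 2 || kw != 2 || wCin != Cin) stop("bad transposed-conv kernel");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = num4(Ho, Wo, Cout, B);
  const size_t slab = (size_t)H * W * Cin, oslab = (size_t)Ho * Wo * Cout;
  for (int s = 0; s < B; ++s) {
    const double *xs = x.begin() + s * slab;
    double *ys = y.begin() + s * oslab;
    for (int co = 0; co < Cout; ++co) {
      double *yc = ys + (size_t)co * Ho * Wo;
      for (size_t q = 0; q < (size_t)Ho * Wo; ++q) yc[q] = b[co];
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xc = xs + (size_t)ci * H * W;
        const double w00 = w[0 + 2 * (0 + 2 * (ci + Cin * co))];
        const double w10 = w[1 + 2 * (0 + 2 * (ci + Cin * co))];
        const double w01 = w[0 + 2 * (1 + 2 * (ci + Cin * co))];
        const double w11 = w[1 + 2 * (1 + 2 * (ci + Cin * co))];
        for (int j = 0; j < W; ++j) {
          const double *xcol = xc + (size_t)j * H;
          double *y0 = yc + (size_t)(2 * j) * Ho;
          double *y1 = yc + (size_t)(2 * j + 1) * Ho;
          for (int i = 0; i < H; ++i) {
            const double v = xcol[i];
            y0[2 * i] += v * w00;
            y0[2 * i + 1] += v * w10;
            y1[2 * i] += v * w01;
            y1[2 * i + 1] += v * w11;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".tconv2_bw")]]
List tconv2_bw(NumericVector x, NumericVector w, NumericVector gy) {
  int H, W, Cin, B, kh, kw, wCin, Cout;
  dims4(x, H, W, Cin, B);
  dims4(w, kh, kw, wCin, Cout);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx = num4(H, W, Cin, B);
  NumericVector gw = num4(2, 2, Cin, Cout);
  NumericVector gb(Cout);
  const size_t slab = (size_t)H * W * Cin, oslab = (size_t)Ho * Wo * Cout;
  for (int s = 0; s < B; ++s) {
    const double *xs = x.begin() + s * slab;
    const double *gs = gy.begin() + s * oslab;
    double *gxs = gx.begin() + s * slab;
    for (int co = 0; co < Cout; ++co) {
      const double *gc = gs + (size_t)co * Ho * Wo;
      double acc = 0.0;
      for (size_t q = 0; q < (size_t)Ho * Wo; ++q) acc += gc[q];
      gb[co] += acc;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xc = xs + (size_t)ci * H * W;
        double *gxc = gxs + (size_t)ci * H * W;
        const size_t wbase = 2 * (0 + 2 * ((size_t)ci + Cin * co));
        const double w00 = w[wbase + 0], w10 = w[wbase + 1];
        const double w01 = w[wbase + 2], w11 = w[wbase + 3];
        double g00 = 0, g10 = 0, g01 = 0, g11 = 0;
        for (int j = 0; j < W; ++j) {
          const double *g0 = gc + (size_t)(2 * j) * Ho;
          const double *g1 = gc + (size_t)(2 * j + 1) * Ho;
          const double *xcol = xc + (size_t)j * H;
          double *gxcol = gxc + (size_t)j * H;
          for (int i = 0; i < H; ++i) {
            const double a = g0[2 * i], bb = g0[2 * i + 1];
            const double cc = g1[2 * i], dd = g1[2 * i + 1];
            gxcol[i] += a * w00 + bb * w10 + cc * w01 + dd * w11;
            const double v = xcol[i];
            g00 += v * a; g10 += v * bb; g01 += v * cc; g11 += v * dd;
          }
        }
        gw[wbase + 0] += g00; gw[wbase + 1] += g10;
        gw[wbase + 2] += g01; gw[wbase + 3] += g11;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".relu_fw")]]
NumericVector relu_fw(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *xs = x.begin();
  double *ys = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) ys[i] = xs[i] > 0 ? xs[i] : 0.0;
  return y;
}

// g * (z > 0), single pass
// [[Rcpp::export(name = ".relu_bw")]]
NumericVector relu_bw(NumericVector g, NumericVector z) {
  if (g.size() != z.size()) stop("relu_bw size mismatch");
  NumericVector y(g.size());
  y.attr("dim") = g.attr("dim");
  const double *gs = g.begin(), *zs = z.begin();
  double *ys = y.begin();
  const R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i) ys[i] = zs[i] > 0 ? gs[i] : 0.0;
  return y;
}

// Inverted dropout using R's RNG stream: returns the dropped activations
// and the scaled keep mask needed by the backward pass.
// [[Rcpp::export(name = ".dropout_fw")]]
List dropout_fw(NumericVector x, double rate) {
  NumericVector y(x.size()), keep(x.size());
  y.attr("dim") = x.attr("dim");
  keep.attr("dim") = x.attr("dim");
  const double q = 1.0 - rate;
  const double *xs = x.begin();
  double *ys = y.begin(), *ks = keep.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double k = (unif_rand() >= rate) ? 1.0 / q : 0.0;
    ks[i] = k;
    ys[i] = xs[i] * k;
  }
  return List::create(_["y"] = y, _["keep"] = keep);
}

// elementwise product (backward of dropout), avoids R temporaries
// [[Rcpp::export(name = ".mul")]]
NumericVector mul(NumericVector a, NumericVector b) {
  if (a.size() != b.size()) stop("mul size mismatch");
  NumericVector y(a.size());
  y.attr("dim") = a.attr("dim");
  const double *as = a.begin(), *bs = b.begin();
  double *ys = y.begin();
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) ys[i] = as[i] * bs[i];
  return y;
}
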