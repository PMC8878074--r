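// Dense numeric kernels for the blur-attention segmentation network.
//
// Feature maps are R arrays with dim = c(N, C, H, W) (batch, channel, row,
// column), column-major, so element (n,c,h,w) sits at
//   n + N*(c + C*(h + H*w)).
// Every learnable operation comes as a fwd/bwd pair; the R-level tape in
// R/autograd.R composes them.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline R_xlen_t I4(int n, int c, int h, int w, int N, int C, int H) {
  return (R_xlen_t)n +
         (R_xlen_t)N * ((R_xlen_t)c + (R_xlen_t)C * ((R_xlen_t)h + (R_xlen_t)H * (R_xlen_t)w));
}

// mirror index without edge repetition (np.pad "reflect"); degenerates to 0
// for a 1-pixel axis
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static NumericVector make4(int N, int C, int H, int W) {
  NumericVector y((R_xlen_t)N * C * H * W);
  y.attr("dim") = IntegerVector::create(N, C, H, W);
  return y;
}

// ---------------------------------------------------------------------------
// conv2d, stride 1, zero padding "same", square odd kernel, optional dilation
// x: (N,Cin,H,W); w: (Cout,Cin,k,k); b: (Cout)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], Cin = xd[1], H = xd[2], W = xd[3];
  const int Cout = wd[0], k = wd[2];
  const int p = dil * (k - 1) / 2;
  const R_xlen_t J = (R_xlen_t)N * H * W;

  arma::mat col(Cin * k * k, J);
  const double* xp = x.begin();
  for (int ci = 0; ci < Cin; ++ci)
    for (int r = 0; r < k; ++r)
      for (int s = 0; s < k; ++s) {
        const int row = s + k * (r + k * ci);
        for (int w2 = 0; w2 < W; ++w2) {
          const int ws = w2 + dil * s - p;
          const bool wok = (ws >= 0 && ws < W);
          for (int h2 = 0; h2 < H; ++h2) {
            const int hs = h2 + dil * r - p;
            const R_xlen_t j0 = (R_xlen_t)N * (h2 + (R_xlen_t)H * w2);
            if (wok && hs >= 0 && hs < H) {
              const double* src = xp + I4(0, ci, hs, ws, N, Cin, H);
              for (int n = 0; n < N; ++n) col(row, j0 + n) = src[n];
            } else {
              for (int n = 0; n < N; ++n) col(row, j0 + n) = 0.0;
            }
          }
        }
      }

  arma::mat Wm(Cout, Cin * k * k);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int r = 0; r < k; ++r)
        for (int s = 0; s < k; ++s)
          Wm(co, s + k * (r + k * ci)) =
            w[(R_xlen_t)co + (R_xlen_t)Cout * (ci + (R_xlen_t)Cin * (r + (R_xlen_t)k * s))];

  arma::mat Y = Wm * col;  // (Cout, J)
  NumericVector y = make4(N, Cout, H, W);
  double* yp = y.begin();
  for (int w2 = 0; w2 < W; ++w2)
    for (int h2 = 0; h2 < H; ++h2) {
      const R_xlen_t j0 = (R_xlen_t)N * (h2 + (R_xlen_t)H * w2);
      for (int co = 0; co < Cout; ++co) {
        const double bb = b[co];
        double* dst = yp + I4(0, co, h2, w2, N, Cout, H);
        for (int n = 0; n < N; ++n) dst[n] = Y(co, j0 + n) + bb;
      }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], Cin = xd[1], H = xd[2], W = xd[3];
  const int Cout = wd[0], k = wd[2];
  const int p = dil * (k - 1) / 2;
  const R_xlen_t J = (R_xlen_t)N * H * W;

  // rebuild the im2col matrix (memory-for-time tradeoff as in fwd)
  arma::mat col(Cin * k * k, J);
  const double* xp = x.begin();
  for (int ci = 0; ci < Cin; ++ci)
    for (int r = 0; r < k; ++r)
      for (int s = 0; s < k; ++s) {
        const int row = s + k * (r + k * ci);
        for (int w2 = 0; w2 < W; ++w2) {
          const int ws = w2 + dil * s - p;
          const bool wok = (ws >= 0 && ws < W);
          for (int h2 = 0; h2 < H; ++h2) {
            const int hs = h2 + dil * r - p;
            const R_xlen_t j0 = (R_xlen_t)N * (h2 + (R_xlen_t)H * w2);
            if (wok && hs >= 0 && hs < H) {
              const double* src = xp + I4(0, ci, hs, ws, N, Cin, H);
              for (int n = 0; n < N; ++n) col(row, j0 + n) = src[n];
            } else {
              for (int n = 0; n < N; ++n) col(row, j0 + n) = 0.0;
            }
          }
        }
      }

  arma::mat Gy(Cout, J);
  const double* gp = gy.begin();
  for (int w2 = 0; w2 < W; ++w2)
    for (int h2 = 0; h2 < H; ++h2) {
      const R_xlen_t j0 = (R_xlen_t)N * (h2 + (R_xlen_t)H * w2);
      for (int co = 0; co < Cout; ++co) {
        const double* src = gp + I4(0, co, h2, w2, N, Cout, H);
        for (int n = 0; n < N; ++n) Gy(co, j0 + n) = src[n];
      }
    }

  arma::mat Wm(Cout, Cin * k * k);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int r = 0; r < k; ++r)
        for (int s = 0; s < k; ++s)
          Wm(co, s + k * (r + k * ci)) =
            w[(R_xlen_t)co + (R_xlen_t)Cout * (ci + (R_xlen_t)Cin * (r + (R_xlen_t)k * s))];

  arma::mat Gw = Gy * col.t();       // (Cout, Cin*k*k)
  arma::mat Gcol = Wm.t() * Gy;      // (Cin*k*k, J)

  NumericVector gx = make4(N, Cin, H, W);
  double* gxp = gx.begin();
  for (int ci = 0; ci < Cin; ++ci)
    for (int r = 0; r < k; ++r)
      for (int s = 0; s < k; ++s) {
        const int row = s + k * (r + k * ci);
        for (int w2 = 0; w2 < W; ++w2) {
          const int ws = w2 + dil * s - p;
          if (ws < 0 || ws >= W) continue;
          for (int h2 = 0; h2 < H; ++h2) {
            const int hs = h2 + dil * r - p;
            if (hs < 0 || hs >= H) continue;
            const R_xlen_t j0 = (R_xlen_t)N * (h2 + (R_xlen_t)H * w2);
            double* dst = gxp + I4(0, ci, hs, ws, N, Cin, H);
            for (int n = 0; n < N; ++n) dst[n] += Gcol(row, j0 + n);
          }
        }
      }

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int r = 0; r < k; ++r)
        for (int s = 0; s < k; ++s)
          gw[(R_xlen_t)co + (R_xlen_t)Cout * (ci + (R_xlen_t)Cin * (r + (R_xlen_t)k * s))] =
            Gw(co, s + k * (r + k * ci));

  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    for (R_xlen_t j = 0; j < J; ++j) acc += Gy(co, j);
    gb[co] = acc;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// transpose conv 3x3, stride 2, pad 1, output padding 1 -> exactly doubles H,W
// w: (Cin, Cout, 3, 3)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_convt2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], Cin = xd[1], H = xd[2], W = xd[3];
  const int Cout = wd[1], k = 3;
  const int Ho = 2 * H, Wo = 2 * W;
  const R_xlen_t J = (R_xlen_t)N * H * W;

  arma::mat X(Cin, J);
  const double* xp = x.begin();
  for (int w2 = 0; w2 < W; ++w2)
    for (int h2 = 0; h2 < H; ++h2) {
      const R_xlen_t j0 = (R_xlen_t)N * (h2 + (R_xlen_t)H * w2);
      for (int ci = 0; ci < Cin; ++ci) {
        const double* src = xp + I4(0, ci, h2, w2, N, Cin, H);
        for (int n = 0; n < N; ++n) X(ci, j0 + n) = src[n];
      }
    }

  arma::mat A(Cin, Cout * k * k);  // A(ci, s + k*(r + k*co)) = w(ci,co,r,s)
  for (int ci = 0; ci < Cin; ++ci)
    for (int co = 0; co < Cout; ++co)
      for (int r = 0; r < k; ++r)
        for (int s = 0; s < k; ++s)
          A(ci, s + k * (r + k * co)) =
            w[(R_xlen_t)ci + (R_xlen_t)Cin * (co + (R_xlen_t)Cout * (r + (R_xlen_t)k * s))];

  arma::mat Yc = A.t() * X;  // (Cout*k*k, J)

  NumericVector y = make4(N, Cout, Ho, Wo);
  double* yp = y.begin();
  for (int co = 0; co < Cout; ++co) {
    const double bb = b[co];
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double* dst = yp + I4(0, co, ho, wo, N, Cout, Ho);
        for (int n = 0; n < N; ++n) dst[n] = bb;
      }
  }
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < k; ++r)
      for (int s = 0; s < k; ++s) {
        const int row = s + k * (r + k * co);
        for (int w2 = 0; w2 < W; ++w2) {
          const int wo = 2 * w2 + s - 1;
          if (wo < 0 || wo >= Wo) continue;
          for (int h2 = 0; h2 < H; ++h2) {
            const int ho = 2 * h2 + r - 1;
            if (ho < 0 || ho >= Ho) continue;
            const R_xlen_t j0 = (R_xlen_t)N * (h2 + (R_xlen_t)H * w2);
            double* dst = yp + I4(0, co, ho, wo, N, Cout, Ho);
            for (int n = 0; n < N; ++n) dst[n] += Yc(row, j0 + n);
          }
        }
      }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], Cin = xd[1], H = xd[2], W = xd[3];
  const int Cout = wd[1], k = 3;
  const int Ho = 2 * H, Wo = 2 * W;
  const R_xlen_t J = (R_xlen_t)N * H * W;

  // gather gy into column form aligned with the forward scatter
  arma::mat Gc(Cout * k * k, J, arma::fill::zeros);
  const double* gp = gy.begin();
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < k; ++r)
      for (int s = 0; s < k; ++s) {
        const int row = s + k * (r + k * co);
        for (int w2 = 0; w2 < W; ++w2) {
          const int wo = 2 * w2 + s - 1;
          if (wo < 0 || wo >= Wo) continue;
          for (int h2 = 0; h2 < H; ++h2) {
            const int ho = 2 * h2 + r - 1;
            if (ho < 0 || ho >= Ho) continue;
            const R_xlen_t j0 = (R_xlen_t)N * (h2 + (R_xlen_t)H * w2);
            const double* src = gp + I4(0, co, ho, wo, N, Cout, Ho);
            for (int n = 0; n < N; ++n) Gc(row, j0 + n) = src[n];
          }
        }
      }

  arma::mat A(Cin, Cout * k * k);
  for (int ci = 0; ci < Cin; ++ci)
    for (int co = 0; co < Cout; ++co)
      for (int r = 0; r < k; ++r)
        for (int s = 0; s < k; ++s)
          A(ci, s + k * (r + k * co)) =
            w[(R_xlen_t)ci + (R_xlen_t)Cin * (co + (R_xlen_t)Cout * (r + (R_xlen_t)k * s))];

  arma::mat X(Cin, J);
  const double* xp = x.begin();
  for (int w2 = 0; w2 < W; ++w2)
    for (int h2 = 0; h2 < H; ++h2) {
      const R_xlen_t j0 = (R_xlen_t)N * (h2 + (R_xlen_t)H * w2);
      for (int ci = 0; ci < Cin; ++ci) {
        const double* src = xp + I4(0, ci, h2, w2, N, Cin, H);
        for (int n = 0; n < N; ++n) X(ci, j0 + n) = src[n];
      }
    }

  arma::mat Gx = A * Gc;            // (Cin, J)
  arma::mat Gw = X * Gc.t();        // (Cin, Cout*k*k)

  NumericVector gx = make4(N, Cin, H, W);
  double* gxp = gx.begin();
  for (int w2 = 0; w2 < W; ++w2)
    for (int h2 = 0; h2 < H; ++h2) {
      const R_xlen_t j0 = (R_xlen_t)N * (h2 + (R_xlen_t)H * w2);
      for (int ci = 0; ci < Cin; ++ci) {
        double* dst = gxp + I4(0, ci, h2, w2, N, Cin, H);
        for (int n = 0; n < N; ++n) dst[n] = Gx(ci, j0 + n);
      }
    }

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  for (int ci = 0; ci < Cin; ++ci)
    for (int co = 0; co < Cout; ++co)
      for (int r = 0; r < k; ++r)
        for (int s = 0; s < k; ++s)
          gw[(R_xlen_t)ci + (R_xlen_t)Cin * (co + (R_xlen_t)Cout * (r + (R_xlen_t)k * s))] =
            Gw(ci, s + k * (r + k * co));

  NumericVector gb(Cout);
  const double* gp2 = gy.begin();
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double* src = gp2 + I4(0, co, ho, wo, N, Cout, Ho);
        for (int n = 0; n < N; ++n) acc += src[n];
      }
    gb[co] = acc;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// blur downsampling: per-channel correlation with a fixed low-pass kernel
// (reflect padding, output-before-subsampling = input size), then subsampling
// every `stride` pixels starting at index 0.  k: K x K matrix.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_blurdown_fwd(NumericVector x, NumericMatrix k, int stride) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int K = k.nrow();
  const int pl = (K - 1) / 2;  // left/top pad; right/bottom gets the remainder
  const int Ho = (H + stride - 1) / stride, Wo = (W + stride - 1) / stride;

  NumericVector y = make4(N, C, Ho, Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  // reflected source rows/cols per output position, hoisted out of the loops
  std::vector<int> rh((size_t)Ho * K), rw((size_t)Wo * K);
  for (int ho = 0; ho < Ho; ++ho)
    for (int r = 0; r < K; ++r) rh[(size_t)ho * K + r] = refl(ho * stride - pl + r, H);
  for (int wo = 0; wo < Wo; ++wo)
    for (int s = 0; s < K; ++s) rw[(size_t)wo * K + s] = refl(wo * stride - pl + s, W);

  const R_xlen_t rowstr = (R_xlen_t)N * C;        // step between rows h
  const R_xlen_t colstr = rowstr * H;             // step between cols w
  const R_xlen_t orow = (R_xlen_t)N * C;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)N * c;
    double* yc = yp + (R_xlen_t)N * c;
    for (int wo = 0; wo < Wo; ++wo) {
      const int* ws = &rw[(size_t)wo * K];
      double* ycol = yc + (R_xlen_t)orow * Ho * wo;
      for (int ho = 0; ho < Ho; ++ho) {
        const int* hs = &rh[(size_t)ho * K];
        double* dst = ycol + orow * ho;
        for (int r = 0; r < K; ++r) {
          const double* xrow = xc + rowstr * hs[r];
          for (int s = 0; s < K; ++s) {
            const double kv = k(r, s);
            if (kv == 0.0) continue;
            const double* src = xrow + colstr * ws[s];
            for (int n = 0; n < N; ++n) dst[n] += kv * src[n];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_blurdown_bwd(NumericVector gy, NumericMatrix k, int stride, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  const int N = gd[0], C = gd[1], Ho = gd[2], Wo = gd[3];
  const int K = k.nrow();
  const int pl = (K - 1) / 2;

  NumericVector gx = make4(N, C, H, W);
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  std::vector<int> rh((size_t)Ho * K), rw((size_t)Wo * K);
  for (int ho = 0; ho < Ho; ++ho)
    for (int r = 0; r < K; ++r) rh[(size_t)ho * K + r] = refl(ho * stride - pl + r, H);
  for (int wo = 0; wo < Wo; ++wo)
    for (int s = 0; s < K; ++s) rw[(size_t)wo * K + s] = refl(wo * stride - pl + s, W);
  const R_xlen_t rowstr = (R_xlen_t)N * C;
  const R_xlen_t colstr = rowstr * H;
  for (int c = 0; c < C; ++c) {
    double* xc = gxp + (R_xlen_t)N * c;
    const double* gc = gp + (R_xlen_t)N * c;
    for (int wo = 0; wo < Wo; ++wo) {
      const int* ws = &rw[(size_t)wo * K];
      const double* gcol = gc + (R_xlen_t)N * C * Ho * wo;
      for (int ho = 0; ho < Ho; ++ho) {
        const int* hs = &rh[(size_t)ho * K];
        const double* src = gcol + (R_xlen_t)N * C * ho;
        for (int r = 0; r < K; ++r) {
          double* xrow = xc + rowstr * hs[r];
          for (int s = 0; s < K; ++s) {
            const double kv = k(r, s);
            if (kv == 0.0) continue;
            double* dst = xrow + colstr * ws[s];
            for (int n = 0; n < N; ++n) dst[n] += kv * src[n];
          }
        }
      }
    }
  }
  return gx;
}

// ---------------------------------------------------------------------------
// dense 2x2 max, stride 1, same output size (windows clamped at borders);
// argmax recorded for the backward pass
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxdense_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y = make4(N, C, H, W);
  IntegerVector arg(x.size());  // linear offset of the winning pixel
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  const R_xlen_t rowstr = (R_xlen_t)N * C;
  const R_xlen_t colstr = rowstr * H;
  for (int c = 0; c < C; ++c) {
    const R_xlen_t oc = (R_xlen_t)N * c;
    for (int w2 = 0; w2 < W; ++w2) {
      const R_xlen_t dw = (w2 + 1 < W) ? colstr : 0;
      for (int h2 = 0; h2 < H; ++h2) {
        const R_xlen_t dh = (h2 + 1 < H) ? rowstr : 0;
        const R_xlen_t o00 = oc + rowstr * h2 + colstr * w2;
        const double* p00 = xp + o00;
        const double* p10 = p00 + dh;
        const double* p01 = p00 + dw;
        const double* p11 = p00 + dh + dw;
        double* dst = yp + o00;
        int* adst = ap + o00;
        for (int n = 0; n < N; ++n) {
          double best = p00[n];
          R_xlen_t bi = o00 + n;
          if (p10[n] > best) { best = p10[n]; bi = o00 + dh + n; }
          if (p01[n] > best) { best = p01[n]; bi = o00 + dw + n; }
          if (p11[n] > best) { best = p11[n]; bi = o00 + dh + dw + n; }
          dst[n] = best;
          adst[n] = (int)bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxdense_bwd(NumericVector gy, IntegerVector arg) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  const double* gp = gy.begin();
  const int* ap = arg.begin();
  double* gxp = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) gxp[ap[i]] += gp[i];
  return gx;
}

// ---------------------------------------------------------------------------
// adaptive average pooling to (Ho, Wo) with floor/ceil block boundaries
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_adaptavg_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y = make4(N, C, Ho, Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = (int)((R_xlen_t)wo * W / Wo), w1 = (int)(((R_xlen_t)wo + 1) * W / Wo);
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = (int)((R_xlen_t)ho * H / Ho), h1 = (int)(((R_xlen_t)ho + 1) * H / Ho);
        const double inv = 1.0 / ((h1 - h0) * (w1 - w0));
        double* dst = yp + I4(0, c, ho, wo, N, C, Ho);
        for (int ws = w0; ws < w1; ++ws)
          for (int hs = h0; hs < h1; ++hs) {
            const double* src = xp + I4(0, c, hs, ws, N, C, H);
            for (int n = 0; n < N; ++n) dst[n] += src[n];
          }
        for (int n = 0; n < N; ++n) dst[n] *= inv;
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_adaptavg_bwd(NumericVector gy, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  const int N = gd[0], C = gd[1], Ho = gd[2], Wo = gd[3];
  NumericVector gx = make4(N, C, H, W);
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = (int)((R_xlen_t)wo * W / Wo), w1 = (int)(((R_xlen_t)wo + 1) * W / Wo);
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = (int)((R_xlen_t)ho * H / Ho), h1 = (int)(((R_xlen_t)ho + 1) * H / Ho);
        const double inv = 1.0 / ((h1 - h0) * (w1 - w0));
        const double* src = gp + I4(0, c, ho, wo, N, C, Ho);
        for (int ws = w0; ws < w1; ++ws)
          for (int hs = h0; hs < h1; ++hs) {
            double* dst = gxp + I4(0, c, hs, ws, N, C, H);
            for (int n = 0; n < N; ++n) dst[n] += inv * src[n];
          }
      }
    }
  return gx;
}

// ---------------------------------------------------------------------------
// nearest-neighbour resize to (Ho, Wo): in = floor(out * in_size / out_size)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_resize_nn_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y = make4(N, C, Ho, Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo) {
      const int ws = (int)((R_xlen_t)wo * W / Wo);
      for (int ho = 0; ho < Ho; ++ho) {
        const int hs = (int)((R_xlen_t)ho * H / Ho);
        const double* src = xp + I4(0, c, hs, ws, N, C, H);
        double* dst = yp + I4(0, c, ho, wo, N, C, Ho);
        for (int n = 0; n < N; ++n) dst[n] = src[n];
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_nn_bwd(NumericVector gy, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  const int N = gd[0], C = gd[1], Ho = gd[2], Wo = gd[3];
  NumericVector gx = make4(N, C, H, W);
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo) {
      const int ws = (int)((R_xlen_t)wo * W / Wo);
      for (int ho = 0; ho < Ho; ++ho) {
        const int hs = (int)((R_xlen_t)ho * H / Ho);
        const double* src = gp + I4(0, c, ho, wo, N, C, Ho);
        double* dst = gxp + I4(0, c, hs, ws, N, C, H);
        for (int n = 0; n < N; ++n) dst[n] += src[n];
      }
    }
  return gx;
}

// ---------------------------------------------------------------------------
// channel reductions -> (N, 1, H, W)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_chanmean_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y = make4(N, 1, H, W);
  const double* xp = x.begin();
  double* yp = y.begin();
  const double inv = 1.0 / C;
  for (int w2 = 0; w2 < W; ++w2)
    for (int h2 = 0; h2 < H; ++h2) {
      double* dst = yp + I4(0, 0, h2, w2, N, 1, H);
      for (int c = 0; c < C; ++c) {
        const double* src = xp + I4(0, c, h2, w2, N, C, H);
        for (int n = 0; n < N; ++n) dst[n] += src[n];
      }
      for (int n = 0; n < N; ++n) dst[n] *= inv;
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_chanmean_bwd(NumericVector gy, int C) {
  IntegerVector gd = gy.attr("dim");
  const int N = gd[0], H = gd[2], W = gd[3];
  NumericVector gx = make4(N, C, H, W);
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  const double inv = 1.0 / C;
  for (int w2 = 0; w2 < W; ++w2)
    for (int h2 = 0; h2 < H; ++h2) {
      const double* src = gp + I4(0, 0, h2, w2, N, 1, H);
      for (int c = 0; c < C; ++c) {
        double* dst = gxp + I4(0, c, h2, w2, N, C, H);
        for (int n = 0; n < N; ++n) dst[n] += inv * src[n];
      }
    }
  return gx;
}

// [[Rcpp::export]]
List cpp_chanmax_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y = make4(N, 1, H, W);
  IntegerVector arg((R_xlen_t)N * H * W);  // winning channel
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int w2 = 0; w2 < W; ++w2)
    for (int h2 = 0; h2 < H; ++h2) {
      const R_xlen_t o = I4(0, 0, h2, w2, N, 1, H);
      for (int n = 0; n < N; ++n) {
        double best = xp[I4(n, 0, h2, w2, N, C, H)];
        int bc = 0;
        for (int c = 1; c < C; ++c) {
          const double v = xp[I4(n, c, h2, w2, N, C, H)];
          if (v > best) { best = v; bc = c; }
        }
        yp[o + n] = best;
        ap[o + n] = bc;
      }
    }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_chanmax_bwd(NumericVector gy, IntegerVector arg, int C) {
  IntegerVector gd = gy.attr("dim");
  const int N = gd[0], H = gd[2], W = gd[3];
  NumericVector gx = make4(N, C, H, W);
  const double* gp = gy.begin();
  const int* ap = arg.begin();
  double* gxp = gx.begin();
  for (int w2 = 0; w2 < W; ++w2)
    for (int h2 = 0; h2 < H; ++h2) {
      const R_xlen_t o = I4(0, 0, h2, w2, N, 1, H);
      for (int n = 0; n < N; ++n)
        gxp[I4(n, ap[o + n], h2, w2, N, C, H)] += gp[o + n];
    }
  return gx;
}

// ---------------------------------------------------------------------------
// 8-connected component labelling of a binary matrix (H x W, column-major);
// labels assigned in row-major raster order of each component's first pixel
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix bin) {
  const int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> qh, qw;
  int next = 0;
  for (int h = 0; h < H; ++h)
    for (int w = 0; w < W; ++w) {
      if (bin(h, w) == 0 || lab(h, w) != 0) continue;
      ++next;
      lab(h, w) = next;
      qh.clear(); qw.clear();
      qh.push_back(h); qw.push_back(w);
      size_t head = 0;
      while (head < qh.size()) {
        const int ch = qh[head], cw = qw[head];
        ++head;
        for (int dh = -1; dh <= 1; ++dh)
          for (int dw = -1; dw <= 1; ++dw) {
            if (dh == 0 && dw == 0) continue;
            const int nh = ch + dh, nw = cw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (bin(nh, nw) != 0 && lab(nh, nw) == 0) {
              lab(nh, nw) = next;
              qh.push_back(nh); qw.push_back(nw);
            }
          }
      }
    }
  return lab;
}
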