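// Low-level NHWC-style (H, W, C, N column-major) tensor kernels backing the
// R-level reverse-mode tape. GEMM via Armadillo (R's BLAS).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::ivec dims4(const NumericVector &x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return arma::ivec{d[0], d[1], d[2], d[3]};
}

// im2col: col is (KH*KW*C) x (Ho*Wo), row index r = kh + KH*kw + KH*KW*c,
// column index j = ho + Ho*wo. Matches the (KH, KW, Cin, Cout) weight layout.
static void im2col(const double *x, int H, int W, int C,
                   int KH, int KW, int stride, int pad,
                   int Ho, int Wo, arma::mat &col) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const int r = kh + KH * kw + KH * KW * c;
        double *crow = col.memptr() + r; // stride col.n_rows between columns
        const size_t nr = col.n_rows;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride + kw - pad;
          if (w < 0 || w >= W) continue;
          const double *xcol = xc + (size_t)H * w;
          const size_t jbase = (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride + kh - pad;
            if (h < 0 || h >= H) continue;
            crow[(jbase + ho) * nr] = xcol[h];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat &col, int H, int W, int C,
                   int KH, int KW, int stride, int pad,
                   int Ho, int Wo, double *gx) {
  const size_t nr = col.n_rows;
  for (int c = 0; c < C; ++c) {
    double *xc = gx + (size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const int r = kh + KH * kw + KH * KW * c;
        const double *crow = col.memptr() + r;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride + kw - pad;
          if (w < 0 || w >= W) continue;
          double *xcol = xc + (size_t)H * w;
          const size_t jbase = (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride + kh - pad;
            if (h < 0 || h >= H) continue;
            xcol[h] += crow[(jbase + ho) * nr];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  arma::ivec dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int KH = dw[0], KW = dw[1], Cout = dw[3];
  if (dw[2] != C) stop("conv2d: channel mismatch");
  const int Ho = (H + 2 * pad - KH) / stride + 1;
  const int Wo = (W + 2 * pad - KW) / stride + 1;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double *>(w.begin()), (size_t)KH * KW * C, Cout, false, true);
  arma::rowvec bv(const_cast<double *>(b.begin()), Cout, false, true);
  arma::mat col((size_t)KH * KW * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, KH, KW, stride, pad, Ho, Wo, col);
    arma::mat Om(y.begin() + (size_t)Ho * Wo * Cout * n, (size_t)Ho * Wo, Cout, false, true);
    Om = col.t() * Wm;
    Om.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad) {
  arma::ivec dx = dims4(x), dw = dims4(w), dy = dims4(gy);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int KH = dw[0], KW = dw[1], Cout = dw[3];
  const int Ho = dy[0], Wo = dy[1];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  arma::mat Wm(const_cast<double *>(w.begin()), (size_t)KH * KW * C, Cout, false, true);
  arma::mat Gw(gw.begin(), (size_t)KH * KW * C, Cout, false, true);
  arma::rowvec Gb(gb.begin(), Cout, false, true);
  arma::mat col((size_t)KH * KW * C, (size_t)Ho * Wo);
  arma::mat gcol((size_t)KH * KW * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, KH, KW, stride, pad, Ho, Wo, col);
    arma::mat Gm(const_cast<double *>(gy.begin()) + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false, true);
    Gw += col * Gm;
    Gb += arma::sum(Gm, 0);
    gcol = Wm * Gm.t();
    col2im(gcol, H, W, C, KH, KW, stride, pad, Ho, Wo, gx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 3x3 stride-2 pad-1 max pooling (ResNet stem); argmax kept for backward.
// [[Rcpp::export(name = ".cpp_maxpool_fwd")]]
List cpp_maxpool_fwd(NumericVector x) {
  arma::ivec dx = dims4(x);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = (H + 2 - 3) / 2 + 1, Wo = (W + 2 - 3) / 2 + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size()); // flat index into x
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const size_t obase = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -INFINITY; int bi = -1;
          for (int kw = 0; kw < 3; ++kw) {
            const int w = wo * 2 + kw - 1;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < 3; ++kh) {
              const int h = ho * 2 + kh - 1;
              if (h < 0 || h >= H) continue;
              const double v = xp[h + (size_t)H * w];
              if (v > best) { best = v; bi = h + H * w; }
            }
          }
          const size_t o = obase + ho + (size_t)Ho * wo;
          y[o] = best;
          idx[o] = bi + (int)((size_t)H * W * (c + (size_t)C * n));
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_bwd")]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nx);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// Bilinear upsampling by integer factor f, half-pixel-center convention.
// [[Rcpp::export(name = ".cpp_upsample_fwd")]]
NumericVector cpp_upsample_fwd(NumericVector x, int f) {
  arma::ivec dx = dims4(x);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = H * f, Wo = W * f;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> i0(Ho), i1(Ho), j0(Wo), j1(Wo);
  std::vector<double> ia(Ho), ja(Wo);
  for (int ho = 0; ho < Ho; ++ho) {
    double s = (ho + 0.5) / f - 0.5;
    int lo = (int)std::floor(s);
    ia[ho] = s - lo;
    i0[ho] = std::min(std::max(lo, 0), H - 1);
    i1[ho] = std::min(std::max(lo + 1, 0), H - 1);
  }
  for (int wo = 0; wo < Wo; ++wo) {
    double s = (wo + 0.5) / f - 0.5;
    int lo = (int)std::floor(s);
    ja[wo] = s - lo;
    j0[wo] = std::min(std::max(lo, 0), W - 1);
    j1[wo] = std::min(std::max(lo + 1, 0), W - 1);
  }
  for (int cn = 0; cn < C * N; ++cn) {
    const double *xp = x.begin() + (size_t)H * W * cn;
    double *yp = y.begin() + (size_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      const double *c0 = xp + (size_t)H * j0[wo], *c1 = xp + (size_t)H * j1[wo];
      const double b = ja[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const double a = ia[ho];
        yp[ho + (size_t)Ho * wo] =
          (1 - a) * ((1 - b) * c0[i0[ho]] + b * c1[i0[ho]]) +
          a * ((1 - b) * c0[i1[ho]] + b * c1[i1[ho]]);
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample_bwd")]]
NumericVector cpp_upsample_bwd(NumericVector gy, int f, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H * f, Wo = W * f;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  std::vector<int> i0(Ho), i1(Ho), j0(Wo), j1(Wo);
  std::vector<double> ia(Ho), ja(Wo);
  for (int ho = 0; ho < Ho; ++ho) {
    double s = (ho + 0.5) / f - 0.5;
    int lo = (int)std::floor(s);
    ia[ho] = s - lo;
    i0[ho] = std::min(std::max(lo, 0), H - 1);
    i1[ho] = std::min(std::max(lo + 1, 0), H - 1);
  }
  for (int wo = 0; wo < Wo; ++wo) {
    double s = (wo + 0.5) / f - 0.5;
    int lo = (int)std::floor(s);
    ja[wo] = s - lo;
    j0[wo] = std::min(std::max(lo, 0), W - 1);
    j1[wo] = std::min(std::max(lo + 1, 0), W - 1);
  }
  for (int cn = 0; cn < C * N; ++cn) {
    const double *gp = gy.begin() + (size_t)Ho * Wo * cn;
    double *xp = gx.begin() + (size_t)H * W * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      const double b = ja[wo];
      double *c0 = xp + (size_t)H * j0[wo], *c1 = xp + (size_t)H * j1[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const double a = ia[ho], g = gp[ho + (size_t)Ho * wo];
        c0[i0[ho]] += (1 - a) * (1 - b) * g;
        c1[i0[ho]] += (1 - a) * b * g;
        c0[i1[ho]] += a * (1 - b) * g;
        c1[i1[ho]] += a * b * g;
      }
    }
  }
  return gx;
}
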