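// Low-level 3D CNN kernels: conv3d (stride 1, 'same' padding) via
// im2col + BLAS GEMM, 2x2x2 max pooling, ReLU, and an IEEE-754 binary16
// round-trip used to emulate half-precision parameter storage.
//
// Tensor layout throughout: column-major R arrays [C, D, H, W, B]
// (channel fastest), so a (C x DHW) matrix view of one sample is free.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// col: (C*k^3) x (D*H*W); row index c + C*(kd + k*(kh + k*kw)),
// column index od + D*(oh + H*ow).  Zero padding of width p.
static void im2col3d(const double* x, int C, int D, int H, int W,
                     int k, int p, arma::mat& col) {
  for (int ow = 0; ow < W; ++ow) {
    for (int oh = 0; oh < H; ++oh) {
      for (int od = 0; od < D; ++od) {
        double* cj = col.colptr(od + (std::size_t)D * (oh + (std::size_t)H * ow));
        for (int kw = 0; kw < k; ++kw) {
          const int w = ow + kw - p;
          const bool w_ok = (w >= 0 && w < W);
          for (int kh = 0; kh < k; ++kh) {
            const int h = oh + kh - p;
            const bool h_ok = (h >= 0 && h < H);
            for (int kd = 0; kd < k; ++kd) {
              const int d = od + kd - p;
              double* cp = cj + (std::size_t)C * (kd + (std::size_t)k * (kh + (std::size_t)k * kw));
              if (w_ok && h_ok && d >= 0 && d < D) {
                const double* xp = x + (std::size_t)C * (d + (std::size_t)D * (h + (std::size_t)H * w));
                std::copy(xp, xp + C, cp);
              } else {
                std::fill(cp, cp + C, 0.0);
              }
            }
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col3d
static void col2im3d(const arma::mat& col, double* gx, int C, int D, int H, int W,
                     int k, int p) {
  std::fill(gx, gx + (std::size_t)C * D * H * W, 0.0);
  for (int ow = 0; ow < W; ++ow) {
    for (int oh = 0; oh < H; ++oh) {
      for (int od = 0; od < D; ++od) {
        const double* cj = col.colptr(od + (std::size_t)D * (oh + (std::size_t)H * ow));
        for (int kw = 0; kw < k; ++kw) {
          const int w = ow + kw - p;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = oh + kh - p;
            if (h < 0 || h >= H) continue;
            for (int kd = 0; kd < k; ++kd) {
              const int d = od + kd - p;
              if (d < 0 || d >= D) continue;
              double* xp = gx + (std::size_t)C * (d + (std::size_t)D * (h + (std::size_t)H * w));
              const double* cp = cj + (std::size_t)C * (kd + (std::size_t)k * (kh + (std::size_t)k * kw));
              for (int c = 0; c < C; ++c) xp[c] += cp[c];
            }
          }
        }
      }
    }
  }
}

static int kernel_from_weight(int wcols, int C) {
  int k = (int)std::lround(std::cbrt((double)wcols / C));
  if (k * k * k * C != wcols)
    stop("weight matrix columns (%d) are not C * k^3 for C = %d", wcols, C);
  return k;
}

// x: [C,D,H,W,B]; w: Cout x (C*k^3); b: length Cout -> y: [Cout,D,H,W,B]
// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericMatrix w, NumericVector b) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 5) stop("conv3d_fwd expects a 5-D [C,D,H,W,B] array");
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3], B = dims[4];
  const int Cout = w.nrow();
  const int k = kernel_from_weight(w.ncol(), C);
  const int p = (k - 1) / 2;
  const std::size_t N = (std::size_t)D * H * W;

  arma::mat wm(w.begin(), Cout, w.ncol(), false);
  arma::vec bv(b.begin(), Cout, false);
  NumericVector y((R_xlen_t)Cout * N * B);
  arma::mat col(w.ncol(), N);
  for (int bi = 0; bi < B; ++bi) {
    im2col3d(x.begin() + (std::size_t)C * N * bi, C, D, H, W, k, p, col);
    arma::mat ym(y.begin() + (std::size_t)Cout * N * bi, Cout, N, false, true);
    ym = wm * col;
    ym.each_col() += bv;
  }
  y.attr("dim") = IntegerVector::create(Cout, D, H, W, B);
  return y;
}

// gradients of conv3d_fwd; gy: [Cout,D,H,W,B].  gx computation can be
// skipped for the first layer of a network.
// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericMatrix w, NumericVector gy,
                bool need_gx) {
  IntegerVector dims = x.attr("dim");
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3], B = dims[4];
  const int Cout = w.nrow();
  const int k = kernel_from_weight(w.ncol(), C);
  const int p = (k - 1) / 2;
  const std::size_t N = (std::size_t)D * H * W;

  arma::mat wm(w.begin(), Cout, w.ncol(), false);
  arma::mat gw(Cout, w.ncol(), arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  NumericVector gx(need_gx ? x.size() : 0);
  arma::mat col(w.ncol(), N), gcol;
  for (int bi = 0; bi < B; ++bi) {
    im2col3d(x.begin() + (std::size_t)C * N * bi, C, D, H, W, k, p, col);
    const arma::mat gym((double*)gy.begin() + (std::size_t)Cout * N * bi,
                        Cout, N, false);
    gw += gym * col.t();
    gb += arma::sum(gym, 1);
    if (need_gx) {
      gcol = wm.t() * gym;
      col2im3d(gcol, gx.begin() + (std::size_t)C * N * bi, C, D, H, W, k, p);
    }
  }
  if (need_gx) gx.attr("dim") = dims;
  return List::create(_["gx"] = need_gx ? (SEXP)gx : R_NilValue,
                      _["gw"] = wrap(gw), _["gb"] = wrap(gb));
}

// 2x2x2 max pooling, stride 2; even D,H,W required.  idx holds 0-based
// linear positions into x of each maximum, consumed by maxpool3d_bwd.
// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x) {
  IntegerVector dims = x.attr("dim");
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3], B = dims[4];
  if (D % 2 || H % 2 || W % 2)
    stop("maxpool3d_fwd needs even spatial/temporal extents, got %dx%dx%d",
         D, H, W);
  const int D2 = D / 2, H2 = H / 2, W2 = W / 2;
  const std::size_t Nin = (std::size_t)C * D * H * W;
  NumericVector y((R_xlen_t)C * D2 * H2 * W2 * B);
  NumericVector idx(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  double* ip = idx.begin();
  std::size_t o = 0;
  for (int bi = 0; bi < B; ++bi) {
    const std::size_t xb = Nin * bi;
    for (int ow = 0; ow < W2; ++ow)
      for (int oh = 0; oh < H2; ++oh)
        for (int od = 0; od < D2; ++od)
          for (int c = 0; c < C; ++c, ++o) {
            double best = -HUGE_VAL;
            std::size_t bestpos = 0;
            for (int dw = 0; dw < 2; ++dw)
              for (int dh = 0; dh < 2; ++dh)
                for (int dd = 0; dd < 2; ++dd) {
                  const std::size_t pos = xb + c +
                    (std::size_t)C * ((2 * od + dd) +
                    (std::size_t)D * ((2 * oh + dh) +
                    (std::size_t)H * (2 * ow + dw)));
                  if (xp[pos] > best) { best = xp[pos]; bestpos = pos; }
                }
            yp[o] = best;
            ip[o] = (double)bestpos;
          }
  }
  y.attr("dim") = IntegerVector::create(C, D2, H2, W2, B);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector gy, NumericVector idx,
                            IntegerVector in_dims) {
  R_xlen_t n = 1;
  for (int i = 0; i < in_dims.size(); ++i) n *= in_dims[i];
  NumericVector gx(n);
  const double* gp = gy.begin();
  const double* ip = idx.begin();
  double* xp = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) xp[(std::size_t)ip[i]] += gp[i];
  gx.attr("dim") = in_dims;
  return gx;
}

// Fused batch-norm + ReLU over a channel-first tensor (channel index =
// i % C).  In train mode, batch statistics are used and the running
// statistics are updated; in eval mode the running statistics apply.
// [[Rcpp::export]]
List bn_relu_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                 NumericVector rmean, NumericVector rvar, bool train,
                 double momentum, double eps) {
  const int C = gamma.size();
  const R_xlen_t n = x.size();
  const double nc = (double)(n / C);
  std::vector<double> mu(C), var(C);
  NumericVector new_rmean = clone(rmean), new_rvar = clone(rvar);
  const double* xp = x.begin();
  if (train) {
    std::vector<double> s1(C, 0.0), s2(C, 0.0);
    for (R_xlen_t i = 0; i < n; i += C)
      for (int c = 0; c < C; ++c) {
        const double v = xp[i + c];
        s1[c] += v;
        s2[c] += v * v;
      }
    for (int c = 0; c < C; ++c) {
      mu[c] = s1[c] / nc;
      var[c] = s2[c] / nc - mu[c] * mu[c];
      new_rmean[c] = (1 - momentum) * rmean[c] + momentum * mu[c];
      new_rvar[c] = (1 - momentum) * rvar[c] + momentum * var[c];
    }
  } else {
    for (int c = 0; c < C; ++c) { mu[c] = rmean[c]; var[c] = rvar[c]; }
  }
  NumericVector invv(C), muv(C);
  std::vector<double> a(C), b(C);
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    invv[c] = inv;
    muv[c] = mu[c];
    a[c] = gamma[c] * inv;
    b[c] = beta[c] - gamma[c] * inv * mu[c];
  }
  NumericVector y(n);
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < n; i += C)
    for (int c = 0; c < C; ++c) {
      const double v = a[c] * xp[i + c] + b[c];
      yp[i + c] = v > 0 ? v : 0;
    }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mu"] = muv, _["inv"] = invv,
                      _["rmean"] = new_rmean, _["rvar"] = new_rvar);
}

// backward of bn_relu_fwd; x is the conv output fed to BN, y the ReLU
// output (used as the ReLU mask)
// [[Rcpp::export]]
List bn_relu_bwd(NumericVector gy, NumericVector x, NumericVector y,
                 NumericVector mu, NumericVector inv, NumericVector gamma) {
  const int C = gamma.size();
  const R_xlen_t n = x.size();
  const double nc = (double)(n / C);
  NumericVector dgamma(C), dbeta(C);
  const double* gp = gy.begin();
  const double* xp = x.begin();
  const double* yp = y.begin();
  for (R_xlen_t i = 0; i < n; i += C)
    for (int c = 0; c < C; ++c) {
      if (yp[i + c] <= 0) continue;
      const double g = gp[i + c];
      dbeta[c] += g;
      dgamma[c] += g * (xp[i + c] - mu[c]) * inv[c];
    }
  NumericVector dx(n);
  double* dp = dx.begin();
  std::vector<double> k0(C), k1(C), k2(C);
  for (int c = 0; c < C; ++c) {
    k0[c] = gamma[c] * inv[c];
    k1[c] = dbeta[c] / nc;
    k2[c] = dgamma[c] / nc;
  }
  for (R_xlen_t i = 0; i < n; i += C)
    for (int c = 0; c < C; ++c) {
      if (yp[i + c] <= 0) { dp[i + c] = 0; continue; }
      const double xhat = (xp[i + c] - mu[c]) * inv[c];
      dp[i + c] = k0[c] * (gp[i + c] - k1[c] - xhat * k2[c]);
    }
  dx.attr("dim") = x.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  double* p = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i)
    if (p[i] < 0) p[i] = 0;
  return y;
}

// gy masked by the forward output (y > 0)
// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector gy, NumericVector y) {
  NumericVector gx = clone(gy);
  double* p = gx.begin();
  const double* yp = y.begin();
  for (R_xlen_t i = 0; i < gx.size(); ++i)
    if (yp[i] <= 0) p[i] = 0;
  return gx;
}

// double -> float -> IEEE binary16 -> double, round-to-nearest-even
static double half_round_one(double v) {
  float f = (float)v;
  uint32_t bits;
  std::memcpy(&bits, &f, 4);
  const uint32_t sign = bits & 0x80000000u;
  int32_t exp = (int32_t)((bits >> 23) & 0xFF) - 127;
  uint32_t mant = bits & 0x7FFFFFu;
  uint16_t h;
  if (exp > 15) {                       // overflow -> +-Inf
    h = (uint16_t)((sign >> 16) | 0x7C00);
  } else if (exp >= -14) {              // normal half
    uint32_t m = mant >> 13;
    const uint32_t rem = mant & 0x1FFFu;
    if (rem > 0x1000u || (rem == 0x1000u && (m & 1u))) ++m;
    h = (uint16_t)((sign >> 16) | ((uint32_t)(exp + 15) << 10) | m);
    if (m > 0x3FFu) h = (uint16_t)((sign >> 16) | ((uint32_t)(exp + 16) << 10));
  } else if (exp >= -25) {              // subnormal half
    const int shift = -exp - 1;
    uint32_t full = mant | 0x800000u;
    uint32_t m = full >> shift;
    const uint32_t rem = full & ((1u << shift) - 1u);
    const uint32_t halfbit = 1u << (shift - 1);
    if (rem > halfbit || (rem == halfbit && (m & 1u))) ++m;
    h = (uint16_t)((sign >> 16) | m);
  } else {
    h = (uint16_t)(sign >> 16);         // underflow -> signed zero
  }
  // decode
  const uint32_t hs = (uint32_t)(h & 0x8000u) << 16;
  const uint32_t he = (h >> 10) & 0x1F;
  const uint32_t hm = h & 0x3FFu;
  uint32_t out;
  if (he == 0x1F) out = hs | 0x7F800000u | (hm << 13);
  else if (he == 0) {
    if (hm == 0) out = hs;
    else {
      int e = -1;
      uint32_t m = hm;
      while (!(m & 0x400u)) { m <<= 1; ++e; }
      out = hs | ((uint32_t)(127 - 15 - e) << 23) | ((m & 0x3FFu) << 13);
    }
  } else out = hs | ((he - 15 + 127) << 23) | (hm << 13);
  std::memcpy(&f, &out, 4);
  return (double)f;
}

// [[Rcpp::export]]
NumericVector round_half_precision(NumericVector x) {
  NumericVector y = clone(x);
  double* p = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i) p[i] = half_round_one(p[i]);
  return y;
}
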