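// Convolution / pooling / resampling kernels for the network module.
//
// Tensor layout follows R column-major arrays with dim (H, W, C, N).
// Convolutions are "same"-padded k x k (k odd) with integer dilation,
// computed by the padded shift-and-gemm scheme: the input plane is copied
// once into a zero-padded buffer, and each of the k^2 kernel taps becomes
// one strided BLAS gemm accumulating into the padded output. The zero
// frame absorbs all row/column wrap-around, so no im2col buffer and no
// boundary special-casing is needed. A single-precision path (the default
// at the R level) halves gemm time; the double path is kept for
// finite-difference gradient verification.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#ifndef FCLEN
# define FCLEN
#endif
using namespace Rcpp;

extern "C" {
void F77_NAME(sgemm)(const char* transa, const char* transb, const int* m,
                     const int* n, const int* k, const float* alpha,
                     const float* a, const int* lda, const float* b,
                     const int* ldb, const float* beta, float* c,
                     const int* ldc FCLEN FCLEN);
}

template <typename T>
struct blas_gemm;
template <>
struct blas_gemm<double> {
  static void run(char ta, char tb, int m, int n, int k, double alpha,
                  const double* a, int lda, const double* b, int ldb,
                  double beta, double* c, int ldc) {
    F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta,
                    c, &ldc FCONE FCONE);
  }
};
template <>
struct blas_gemm<float> {
  static void run(char ta, char tb, int m, int n, int k, float alpha,
                  const float* a, int lda, const float* b, int ldb,
                  float beta, float* c, int ldc) {
    F77_CALL(sgemm)(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta,
                    c, &ldc FCONE FCONE);
  }
};

// copy one image's planes into a zero-framed padded buffer (pad = r*dil)
template <typename T>
static void pad_planes(const double* x, int H, int W, int C, int pad, T* xp) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const long np = (long)Hp * Wp;
  std::fill(xp, xp + np * C, (T)0);
  for (int c = 0; c < C; ++c) {
    const double* src = x + (long)c * H * W;
    T* dst = xp + (long)c * np + (long)pad * Hp + pad;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) dst[(long)w * Hp + h] = (T)src[(long)w * H + h];
  }
}

// extract the k^2 tap matrices (Cin x Cout each) from the (k,k,Cin,Cout) kernel
template <typename T>
static void split_taps(const NumericVector& w, int k, int Cin, int Cout,
                       std::vector<T>& taps) {
  taps.resize((size_t)k * k * Cin * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki)
          taps[((size_t)(ki + k * kj) * Cin * Cout) + c + (size_t)Cin * co] =
            (T)w[ki + k * (kj + k * (c + (long)Cin * co))];
}

template <typename T>
static void conv_fwd_T(const NumericVector& x, const NumericVector& w,
                       const NumericVector& b, int H, int W, int Cin, int N,
                       int k, int Cout, int dil, NumericVector& y) {
  const long HW = (long)H * W;
  const int r = (k - 1) / 2, pad = r * dil;
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const long np = (long)Hp * Wp;
  std::vector<T> xp(np * Cin), yp(np * Cout), taps;
  split_taps<T>(w, k, Cin, Cout, taps);
  for (int n = 0; n < N; ++n) {
    pad_planes<T>(&x[0] + n * HW * Cin, H, W, Cin, pad, xp.data());
    std::fill(yp.begin(), yp.end(), (T)0);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const long s = (long)(ki - r) * dil + (long)(kj - r) * dil * Hp;
        const long r0 = std::max(0L, -s), r1 = np - std::max(0L, s);
        blas_gemm<T>::run('N', 'N', (int)(r1 - r0), Cout, Cin, (T)1,
                          xp.data() + r0 + s, (int)np,
                          taps.data() + (size_t)(ki + k * kj) * Cin * Cout, Cin,
                          (T)1, yp.data() + r0, (int)np);
      }
    double* out = &y[0] + n * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      const T* src = yp.data() + (long)co * np + (long)pad * Hp + pad;
      const double bc = b[co];
      double* dst = out + (long)co * HW;
      for (int w2 = 0; w2 < W; ++w2)
        for (int h = 0; h < H; ++h)
          dst[(long)w2 * H + h] = (double)src[(long)w2 * Hp + h] + bc;
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector conv2d_fwd(const NumericVector& x, const NumericVector& w,
                         const NumericVector& b, int dil, bool use_float) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("conv2d: weight/input channel mismatch");
  NumericVector y((long)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  if (use_float) conv_fwd_T<float>(x, w, b, H, W, Cin, N, k, Cout, dil, y);
  else conv_fwd_T<double>(x, w, b, H, W, Cin, N, k, Cout, dil, y);
  return y;
}

template <typename T>
static void conv_bwd_T(const NumericVector& x, const NumericVector& w,
                       const NumericVector& gy, int H, int W, int Cin, int N,
                       int k, int Cout, int dil,
                       NumericVector& gx, NumericVector& gw, NumericVector& gb) {
  const long HW = (long)H * W;
  const int r = (k - 1) / 2, pad = r * dil;
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const long np = (long)Hp * Wp;
  std::vector<T> xp(np * Cin), gyp(np * Cout), gxp(np * Cin), taps,
      gtaps((size_t)k * k * Cin * Cout, (T)0);
  split_taps<T>(w, k, Cin, Cout, taps);
  std::vector<double> gbv(Cout, 0.0);
  for (int n = 0; n < N; ++n) {
    pad_planes<T>(&x[0] + n * HW * Cin, H, W, Cin, pad, xp.data());
    pad_planes<T>(&gy[0] + n * HW * Cout, H, W, Cout, pad, gyp.data());
    std::fill(gxp.begin(), gxp.end(), (T)0);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const long s = (long)(ki - r) * dil + (long)(kj - r) * dil * Hp;
        const long r0 = std::max(0L, -s), r1 = np - std::max(0L, s);
        const int m = (int)(r1 - r0);
        T* tap = taps.data() + (size_t)(ki + k * kj) * Cin * Cout;
        T* gtap = gtaps.data() + (size_t)(ki + k * kj) * Cin * Cout;
        // gXp[r + s] += gYp[r] * W_tap^T
        blas_gemm<T>::run('N', 'T', m, Cin, Cout, (T)1,
                          gyp.data() + r0, (int)np, tap, Cin,
                          (T)1, gxp.data() + r0 + s, (int)np);
        // gW_tap += Xp[r + s]^T * gYp[r]
        blas_gemm<T>::run('T', 'N', Cin, Cout, m, (T)1,
                          xp.data() + r0 + s, (int)np,
                          gyp.data() + r0, (int)np,
                          (T)1, gtap, Cin);
      }
    for (int co = 0; co < Cout; ++co) {
      const double* gp = &gy[0] + n * HW * Cout + (long)co * HW;
      double s = 0;
      for (long i = 0; i < HW; ++i) s += gp[i];
      gbv[co] += s;
    }
    double* gout = &gx[0] + n * HW * Cin;
    for (int c = 0; c < Cin; ++c) {
      const T* src = gxp.data() + (long)c * np + (long)pad * Hp + pad;
      double* dst = gout + (long)c * HW;
      for (int w2 = 0; w2 < W; ++w2)
        for (int h = 0; h < H; ++h)
          dst[(long)w2 * H + h] = (double)src[(long)w2 * Hp + h];
    }
  }
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki)
          gw[ki + k * (kj + k * (c + (long)Cin * co))] =
            (double)gtaps[((size_t)(ki + k * kj) * Cin * Cout) + c + (size_t)Cin * co];
  for (int co = 0; co < Cout; ++co) gb[co] = gbv[co];
}

// [[Rcpp::export(rng = false)]]
List conv2d_bwd(const NumericVector& x, const NumericVector& w,
                const NumericVector& gy, int dil, bool use_float) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  NumericVector gx((long)H * W * Cin * N), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  if (use_float) conv_bwd_T<float>(x, w, gy, H, W, Cin, N, k, Cout, dil, gx, gw, gb);
  else conv_bwd_T<double>(x, w, gy, H, W, Cin, N, k, Cout, dil, gx, gw, gb);
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// [[Rcpp::export(rng = false)]]
List maxpool2_fwd(const NumericVector& x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((long)Ho * Wo * C * N);
  IntegerVector idx(y.size()); // 0-based linear index of argmax in x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  long o = 0;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xp = &x[0] + cn * H * W;
    const long base = cn * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        long i00 = (long)(2 * w) * H + 2 * h;
        long best = i00;
        double v = xp[i00];
        if (xp[i00 + 1] > v) { v = xp[i00 + 1]; best = i00 + 1; }
        if (xp[i00 + H] > v) { v = xp[i00 + H]; best = i00 + H; }
        if (xp[i00 + H + 1] > v) { v = xp[i00 + H + 1]; best = i00 + H + 1; }
        y[o] = v;
        idx[o++] = (int)(base + best);
      }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export(rng = false)]]
NumericVector maxpool2_bwd(const IntegerVector& idx, const NumericVector& gy,
                           const IntegerVector& xdim) {
  NumericVector gx((long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (long i = 0; i < (long)gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// Bilinear 2x upsampling, half-pixel-centers convention: output sample i maps
// to input coordinate i/2 - 1/4, so even outputs mix (1/4, 3/4) with the
// previous input sample and odd outputs (3/4, 1/4) with the next, clamped at
// the borders. Separable; applied along rows then columns.
static void up1d(const double* x, int n, double* y) {
  y[0] = x[0];
  for (int j = 0; j < n; ++j) {
    if (j > 0) y[2 * j] = 0.25 * x[j - 1] + 0.75 * x[j];
    y[2 * j + 1] = (j < n - 1) ? 0.75 * x[j] + 0.25 * x[j + 1] : x[j];
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector upsample2x_fwd(const NumericVector& x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<double> tmp((long)Ho * W);
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xp = &x[0] + cn * H * W;
    double* yp = &y[0] + cn * (long)Ho * Wo;
    for (int w = 0; w < W; ++w) up1d(xp + (long)w * H, H, &tmp[(long)w * Ho]);
    // column pass: each output column is an axpy of two contiguous columns
    for (int j = 0; j < W; ++j) {
      const double* cur = &tmp[(long)j * Ho];
      double* even = yp + (long)(2 * j) * Ho;
      double* odd = even + Ho;
      if (j == 0) std::copy(cur, cur + Ho, even);
      else {
        const double* prev = cur - Ho;
        for (int h = 0; h < Ho; ++h) even[h] = 0.25 * prev[h] + 0.75 * cur[h];
      }
      if (j < W - 1) {
        const double* nxt = cur + Ho;
        for (int h = 0; h < Ho; ++h) odd[h] = 0.75 * cur[h] + 0.25 * nxt[h];
      } else std::copy(cur, cur + Ho, odd);
    }
  }
  return y;
}

static void up1d_adj(const double* gy, int n, double* gx) {
  // adjoint of up1d: gx has length n, gy length 2n
  std::fill(gx, gx + n, 0.0);
  gx[0] += gy[0];
  for (int j = 0; j < n; ++j) {
    if (j > 0) { gx[j - 1] += 0.25 * gy[2 * j]; gx[j] += 0.75 * gy[2 * j]; }
    if (j < n - 1) { gx[j] += 0.75 * gy[2 * j + 1]; gx[j + 1] += 0.25 * gy[2 * j + 1]; }
    else gx[j] += gy[2 * j + 1];
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector upsample2x_bwd(const NumericVector& gy) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx((long)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<double> tmp((long)H * Wo);
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* gyp = &gy[0] + cn * (long)Ho * Wo;
    double* gxp = &gx[0] + cn * (long)H * W;
    // adjoint along rows (height) first
    for (int w = 0; w < Wo; ++w) up1d_adj(gyp + (long)w * Ho, H, &tmp[(long)w * H]);
    // adjoint column pass, accumulating contiguous column axpys
    std::fill(gxp, gxp + (long)H * W, 0.0);
    for (int j = 0; j < W; ++j) {
      const double* even = &tmp[(long)(2 * j) * H];
      const double* odd = even + H;
      double* cur = gxp + (long)j * H;
      if (j == 0) for (int h = 0; h < H; ++h) cur[h] += even[h];
      else {
        double* prev = cur - H;
        for (int h = 0; h < H; ++h) {
          prev[h] += 0.25 * even[h];
          cur[h] += 0.75 * even[h];
        }
      }
      if (j < W - 1) {
        double* nxt = cur + H;
        for (int h = 0; h < H; ++h) {
          cur[h] += 0.75 * odd[h];
          nxt[h] += 0.25 * odd[h];
        }
      } else for (int h = 0; h < H; ++h) cur[h] += odd[h];
    }
  }
  return gx;
}

// ---- fused pointwise kernels (single pass; the R-level equivalents were
// ---- memory-bound and dominated training time) ------------------------------

// [[Rcpp::export(rng = false)]]
List bn_relu_fwd(const NumericVector& x, const NumericVector& gamma,
                 const NumericVector& beta, const NumericVector& rmean,
                 const NumericVector& rvar, bool training, double momentum,
                 double eps, bool relu) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const long HW = (long)H * W;
  const double nper = (double)HW * N;
  NumericVector mu(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xp = &x[0] + ((long)n * C + c) * HW;
        for (long i = 0; i < HW; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
      }
      mu[c] = s / nper;
      var[c] = s2 / nper - mu[c] * mu[c];
      if (var[c] < 0) var[c] = 0;
    }
  } else {
    for (int c = 0; c < C; ++c) { mu[c] = rmean[c]; var[c] = rvar[c]; }
  }
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector sdv(C);
  for (int c = 0; c < C; ++c) sdv[c] = std::sqrt(var[c] + eps);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double sc = gamma[c] / sdv[c], sh = beta[c] - mu[c] * sc;
      const double* xp = &x[0] + ((long)n * C + c) * HW;
      double* yp = &y[0] + ((long)n * C + c) * HW;
      if (relu) for (long i = 0; i < HW; ++i) {
        double v = xp[i] * sc + sh;
        yp[i] = v > 0 ? v : 0;
      }
      else for (long i = 0; i < HW; ++i) yp[i] = xp[i] * sc + sh;
    }
  List out = List::create(Named("y") = y, Named("mu") = mu, Named("sd") = sdv);
  if (training) {
    NumericVector rm2(C), rv2(C);
    const double unb = nper > 1 ? nper / (nper - 1) : 1.0;
    for (int c = 0; c < C; ++c) {
      rm2[c] = (1 - momentum) * rmean[c] + momentum * mu[c];
      rv2[c] = (1 - momentum) * rvar[c] + momentum * var[c] * unb;
    }
    out["rmean"] = rm2;
    out["rvar"] = rv2;
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List bn_relu_bwd(const NumericVector& x, const NumericVector& y,
                 const NumericVector& g, const NumericVector& gamma,
                 const NumericVector& mu, const NumericVector& sdv,
                 bool training, bool relu) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const long HW = (long)H * W;
  const double nper = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    const double m = mu[c], sd = sdv[c];
    for (int n = 0; n < N; ++n) {
      const long off = ((long)n * C + c) * HW;
      const double* xp = &x[0] + off;
      const double* yp = &y[0] + off;
      const double* gp = &g[0] + off;
      for (long i = 0; i < HW; ++i) {
        const double gm = (relu && yp[i] <= 0) ? 0 : gp[i];
        s1 += gm;
        s2 += gm * (xp[i] - m) / sd;
      }
    }
    dgamma[c] = s2;
    dbeta[c] = s1;
    const double sc = gamma[c] / sd;
    for (int n = 0; n < N; ++n) {
      const long off = ((long)n * C + c) * HW;
      const double* xp = &x[0] + off;
      const double* yp = &y[0] + off;
      const double* gp = &g[0] + off;
      double* gxp = &gx[0] + off;
      if (training) {
        const double a = s1 / nper, b = s2 / nper;
        for (long i = 0; i < HW; ++i) {
          const double gm = (relu && yp[i] <= 0) ? 0 : gp[i];
          gxp[i] = sc * (gm - a - (xp[i] - m) / sd * b);
        }
      } else {
        for (long i = 0; i < HW; ++i) {
          const double gm = (relu && yp[i] <= 0) ? 0 : gp[i];
          gxp[i] = sc * gm;
        }
      }
    }
  }
  return List::create(Named("gx") = gx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// [[Rcpp::export(rng = false)]]
NumericVector relu_fwd(const NumericVector& x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (long i = 0; i < (long)x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0;
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector relu_bwd(const NumericVector& y, const NumericVector& g) {
  NumericVector gx(g.size());
  gx.attr("dim") = g.attr("dim");
  for (long i = 0; i < (long)g.size(); ++i) gx[i] = y[i] > 0 ? g[i] : 0;
  return gx;
}

// [[Rcpp::export(rng = false)]]
NumericVector sigmoid_fwd(const NumericVector& x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (long i = 0; i < (long)x.size(); ++i) y[i] = 1.0 / (1.0 + std::exp(-x[i]));
  return y;
}

// channel-axis concatenation of (H, W, Ci, N) arrays
// [[Rcpp::export(rng = false)]]
NumericVector concat_fwd(const List& xs) {
  const int m = xs.size();
  std::vector<const double*> ptr(m);
  std::vector<long> sz(m);
  IntegerVector d0 = as<NumericVector>(xs[0]).attr("dim");
  const int H = d0[0], W = d0[1], N = d0[3];
  const long HW = (long)H * W;
  int Ctot = 0;
  std::vector<NumericVector> keep;
  for (int i = 0; i < m; ++i) {
    NumericVector xi = xs[i];
    keep.push_back(xi);
    IntegerVector di = xi.attr("dim");
    Ctot += di[2];
    sz[i] = (long)di[2] * HW;
    ptr[i] = &xi[0];
  }
  NumericVector out((long)HW * Ctot * N);
  out.attr("dim") = IntegerVector::create(H, W, Ctot, N);
  double* op = &out[0];
  for (int n = 0; n < N; ++n)
    for (int i = 0; i < m; ++i) {
      std::copy(ptr[i] + n * sz[i], ptr[i] + (n + 1) * sz[i], op);
      op += sz[i];
    }
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericVector slice_channels(const NumericVector& x, int from, int len) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const long HW = (long)H * W;
  NumericVector out(HW * (long)len * N);
  out.attr("dim") = IntegerVector::create(H, W, len, N);
  for (int n = 0; n < N; ++n)
    std::copy(&x[0] + ((long)n * C + from - 1) * HW,
              &x[0] + ((long)n * C + from - 1 + len) * HW,
              &out[0] + (long)n * len * HW);
  return out;
}

// ---- multi-input convolution -----------------------------------------------
// conv(concat(x1..xm), W) == sum_i conv(xi, Wi): implementing the split form
// avoids materializing channel concatenations anywhere in the network.

template <typename T>
static void conv_multi_fwd_T(const List& xs, const List& ws,
                             const NumericVector& b, int H, int W, int N,
                             int k, int Cout, int dil, NumericVector& y) {
  const long HW = (long)H * W;
  const int r = (k - 1) / 2, pad = r * dil;
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const long np = (long)Hp * Wp;
  const int m = xs.size();
  std::vector<NumericVector> xv(m), wv(m);
  std::vector<int> cins(m);
  int cmax = 0;
  for (int i = 0; i < m; ++i) {
    xv[i] = as<NumericVector>(xs[i]);
    wv[i] = as<NumericVector>(ws[i]);
    IntegerVector d = xv[i].attr("dim");
    cins[i] = d[2];
    cmax = std::max(cmax, d[2]);
  }
  std::vector<T> xp(np * cmax), yp(np * Cout), taps;
  for (int n = 0; n < N; ++n) {
    std::fill(yp.begin(), yp.end(), (T)0);
    for (int i = 0; i < m; ++i) {
      const int Cin = cins[i];
      split_taps<T>(wv[i], k, Cin, Cout, taps);
      pad_planes<T>(&xv[i][0] + n * HW * Cin, H, W, Cin, pad, xp.data());
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          const long s = (long)(ki - r) * dil + (long)(kj - r) * dil * Hp;
          const long r0 = std::max(0L, -s), r1 = np - std::max(0L, s);
          blas_gemm<T>::run('N', 'N', (int)(r1 - r0), Cout, Cin, (T)1,
                            xp.data() + r0 + s, (int)np,
                            taps.data() + (size_t)(ki + k * kj) * Cin * Cout, Cin,
                            (T)1, yp.data() + r0, (int)np);
        }
    }
    double* out = &y[0] + n * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      const T* src = yp.data() + (long)co * np + (long)pad * Hp + pad;
      const double bc = b[co];
      double* dst = out + (long)co * HW;
      for (int w2 = 0; w2 < W; ++w2)
        for (int h = 0; h < H; ++h)
          dst[(long)w2 * H + h] = (double)src[(long)w2 * Hp + h] + bc;
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector conv_multi_fwd(const List& xs, const List& ws,
                             const NumericVector& b, int dil, bool use_float) {
  NumericVector x0 = xs[0], w0 = as<NumericVector>(ws[0]);
  IntegerVector xd = x0.attr("dim"), wd = w0.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  NumericVector y((long)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  if (use_float) conv_multi_fwd_T<float>(xs, ws, b, H, W, N, k, Cout, dil, y);
  else conv_multi_fwd_T<double>(xs, ws, b, H, W, N, k, Cout, dil, y);
  return y;
}

template <typename T>
static void conv_multi_bwd_T(const List& xs, const List& ws,
                             const NumericVector& gy, int H, int W, int N,
                             int k, int Cout, int dil,
                             List& gxs, List& gws, NumericVector& gb) {
  const long HW = (long)H * W;
  const int r = (k - 1) / 2, pad = r * dil;
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const long np = (long)Hp * Wp;
  const int m = xs.size();
  std::vector<NumericVector> xv(m), wv(m), gxv(m), gwv(m);
  std::vector<int> cins(m);
  int cmax = 0;
  for (int i = 0; i < m; ++i) {
    xv[i] = as<NumericVector>(xs[i]);
    wv[i] = as<NumericVector>(ws[i]);
    IntegerVector d = xv[i].attr("dim");
    cins[i] = d[2];
    cmax = std::max(cmax, d[2]);
    gxv[i] = NumericVector((long)HW * d[2] * N);
    gxv[i].attr("dim") = d;
    gwv[i] = NumericVector(wv[i].size());
    gwv[i].attr("dim") = wv[i].attr("dim");
  }
  std::vector<T> xp(np * cmax), gyp(np * Cout), gxp(np * cmax), taps;
  std::vector<std::vector<T>> gtaps(m);
  for (int i = 0; i < m; ++i) gtaps[i].assign((size_t)k * k * cins[i] * Cout, (T)0);
  for (int n = 0; n < N; ++n) {
    pad_planes<T>(&gy[0] + n * HW * Cout, H, W, Cout, pad, gyp.data());
    for (int i = 0; i < m; ++i) {
      const int Cin = cins[i];
      split_taps<T>(wv[i], k, Cin, Cout, taps);
      pad_planes<T>(&xv[i][0] + n * HW * Cin, H, W, Cin, pad, xp.data());
      std::fill(gxp.begin(), gxp.begin() + np * Cin, (T)0);
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          const long s = (long)(ki - r) * dil + (long)(kj - r) * dil * Hp;
          const long r0 = std::max(0L, -s), r1 = np - std::max(0L, s);
          const int mm = (int)(r1 - r0);
          T* tap = taps.data() + (size_t)(ki + k * kj) * Cin * Cout;
          T* gtap = gtaps[i].data() + (size_t)(ki + k * kj) * Cin * Cout;
          blas_gemm<T>::run('N', 'T', mm, Cin, Cout, (T)1,
                            gyp.data() + r0, (int)np, tap, Cin,
                            (T)1, gxp.data() + r0 + s, (int)np);
          blas_gemm<T>::run('T', 'N', Cin, Cout, mm, (T)1,
                            xp.data() + r0 + s, (int)np,
                            gyp.data() + r0, (int)np,
                            (T)1, gtap, Cin);
        }
      double* gout = &gxv[i][0] + n * HW * Cin;
      for (int c = 0; c < Cin; ++c) {
        const T* src = gxp.data() + (long)c * np + (long)pad * Hp + pad;
        double* dst = gout + (long)c * HW;
        for (int w2 = 0; w2 < W; ++w2)
          for (int h = 0; h < H; ++h)
            dst[(long)w2 * H + h] = (double)src[(long)w2 * Hp + h];
      }
    }
    for (int co = 0; co < Cout; ++co) {
      const double* gp = &gy[0] + n * HW * Cout + (long)co * HW;
      double s = 0;
      for (long j = 0; j < HW; ++j) s += gp[j];
      gb[co] += s;
    }
  }
  for (int i = 0; i < m; ++i) {
    const int Cin = cins[i];
    for (int co = 0; co < Cout; ++co)
      for (int c = 0; c < Cin; ++c)
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki)
            gwv[i][ki + k * (kj + k * (c + (long)Cin * co))] =
              (double)gtaps[i][((size_t)(ki + k * kj) * Cin * Cout) + c + (size_t)Cin * co];
    gxs[i] = gxv[i];
    gws[i] = gwv[i];
  }
}

// [[Rcpp::export(rng = false)]]
List conv_multi_bwd(const List& xs, const List& ws, const NumericVector& gy,
                    int dil, bool use_float) {
  NumericVector x0 = xs[0], w0 = as<NumericVector>(ws[0]);
  IntegerVector xd = x0.attr("dim"), wd = w0.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int m = xs.size();
  List gxs(m), gws(m);
  NumericVector gb(Cout);
  if (use_float) conv_multi_bwd_T<float>(xs, ws, gy, H, W, N, k, Cout, dil, gxs, gws, gb);
  else conv_multi_bwd_T<double>(xs, ws, gy, H, W, N, k, Cout, dil, gxs, gws, gb);
  return List::create(Named("gxs") = gxs, Named("gws") = gws, Named("gb") = gb);
}
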