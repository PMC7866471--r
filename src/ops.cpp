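// Convolution, transposed-convolution and fused batch-norm/LeakyReLU
// kernels for the U-Net.
//
// Array layout follows R's column-major convention throughout:
//   activations  (H, W, C, N)   -- row index fastest
//   conv weights (k, k, Cin, Cout)
// Convolutions run as one im2col + GEMM over the whole batch (patch rows of
// all samples stacked), in single precision: the feature-map GEMMs here are
// small and skinny, where float halves memory traffic; parameters, batch
// statistics and losses stay double on the R side. The transposed
// convolution is the adjoint of a strided convolution (col2im scatter), so
// both ops share the same two patch-matrix primitives.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::fmat;

static inline int conv_out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Fill rows [n*L, (n+1)*L) of the batched patch matrix colsT
// ((N*L) x (k*k*C)) from sample n. Casts double -> float on the fly.
static void im2colT_one(const double* x, int H, int W, int C, int k, int s,
                        int p, fmat& colsT, std::size_t row0) {
  const int Ho = conv_out_dim(H, k, s, p);
  const int Wo = conv_out_dim(W, k, s, p);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)H * W * c;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        float* dst = colsT.colptr(i + k * (j + k * c)) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + j;
          float* dcol = dst + (std::size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) dcol[ho] = 0.0f;
          } else {
            const double* xcol = xc + (std::size_t)H * wi;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * s - p + i;
              dcol[ho] = (hi >= 0 && hi < H) ? (float)xcol[hi] : 0.0f;
            }
          }
        }
      }
    }
  }
}

// Adjoint: scatter-add rows [row0, row0+L) of colsT into one sample image.
static void col2imT_one(const fmat& colsT, int H, int W, int C, int k, int s,
                        int p, double* x, std::size_t row0) {
  const int Ho = conv_out_dim(H, k, s, p);
  const int Wo = conv_out_dim(W, k, s, p);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (std::size_t)H * W * c;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const float* src = colsT.colptr(i + k * (j + k * c)) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + j;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (std::size_t)H * wi;
          const float* scol = src + (std::size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s - p + i;
            if (hi >= 0 && hi < H) xcol[hi] += scol[ho];
          }
        }
      }
    }
  }
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector dims4(const NumericVector& a, const char* what) {
  IntegerVector d(a.attr("dim"));
  if (d.size() != 4) stop("%s must be a 4-d array", what);
  return d;
}

static fmat to_fmat(const NumericVector& v, int nrow, int ncol) {
  fmat out(nrow, ncol);
  const double* src = v.begin();
  float* dst = out.memptr();
  const std::size_t n = (std::size_t)nrow * ncol;
  for (std::size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

// Gather the (L, C, n) blocks of a (Ho, Wo, C, N) array into a ((N*L) x C)
// float matrix whose row index is l + L*n.
static fmat gather_LC(const NumericVector& a, int L, int C, int N) {
  fmat out((std::size_t)L * N, C);
  for (int n = 0; n < N; ++n) {
    const double* an = a.begin() + (std::size_t)L * C * n;
    for (int c = 0; c < C; ++c) {
      const double* src = an + (std::size_t)L * c;
      float* dst = out.colptr(c) + (std::size_t)L * n;
      for (int l = 0; l < L; ++l) dst[l] = (float)src[l];
    }
  }
  return out;
}


// ---- fast path: 3x3, stride 1, pad 1 -------------------------------------
//
// The image stack (all samples) is copied once into a zero-padded
// (H+2) x (W+2) plane per sample and channel, stacked into one tall
// ((N*P) x C) float matrix with a zero guard block at each end. Each of the
// nine kernel taps is then a single GEMM on a row-shifted view of that
// matrix; no patch matrix is ever materialized. Outputs at padding
// positions are junk and are simply not copied out; row shifts never read
// across a sample boundary into another sample's interior because every
// interior pixel's 3x3 neighbourhood lies inside its own padded plane.

static void pad_stack(const double* x, int H, int W, int C, int N,
                      int guard, fmat& Xp) {
  const int Hp = H + 2, Wp = W + 2;
  const std::size_t P = (std::size_t)Hp * Wp;
  Xp.zeros();
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (std::size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (std::size_t)H * W * c;
      float* dst = Xp.colptr(c) + guard + P * n;
      for (int w = 0; w < W; ++w) {
        const double* scol = xc + (std::size_t)H * w;
        float* dcol = dst + (std::size_t)Hp * (w + 1) + 1;
        for (int h = 0; h < H; ++h) dcol[h] = (float)scol[h];
      }
    }
  }
}

static void unpad_stack(const fmat& Yp, int H, int W, int C, int N,
                        const double* bias, double* out) {
  const int Hp = H + 2, Wp = W + 2;
  const std::size_t P = (std::size_t)Hp * Wp;
  for (int n = 0; n < N; ++n) {
    double* on = out + (std::size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      const float* src = Yp.colptr(c) + P * n;
      double* oc = on + (std::size_t)H * W * c;
      const double bc = bias ? bias[c] : 0.0;
      for (int w = 0; w < W; ++w) {
        const float* scol = src + (std::size_t)Hp * (w + 1) + 1;
        double* dcol = oc + (std::size_t)H * w;
        for (int h = 0; h < H; ++h) dcol[h] = (double)scol[h] + bc;
      }
    }
  }
}

static NumericVector conv3_fwd(const NumericVector& x, const NumericVector& w,
                               const NumericVector& b, int H, int W, int C,
                               int N, int Cout) {
  const int Hp = H + 2, Wp = W + 2;
  const std::size_t P = (std::size_t)Hp * Wp;
  const int guard = Hp + 2;
  fmat Xp((std::size_t)P * N + 2 * guard, C);
  pad_stack(x.begin(), H, W, C, N, guard, Xp);
  fmat Wm = to_fmat(w, 9 * C, Cout);  // rows ordered (i, j, c)

  fmat Yp((std::size_t)P * N, Cout, arma::fill::zeros);
  for (int j = 0; j < 3; ++j) {
    for (int i = 0; i < 3; ++i) {
      // tap (i, j) reads input pixel (h + i - 1, w + j - 1); in padded
      // coordinates the source row of output pixel q is q + (i-1) + Hp*(j-1)
      const long off = (i - 1) + Hp * (j - 1);
      fmat Wo(C, Cout);
      for (int c = 0; c < C; ++c)
        for (int co = 0; co < Cout; ++co)
          Wo(c, co) = Wm(i + 3 * j + 9 * c, co);
      Yp += Xp.rows(guard + off, guard + off + P * N - 1) * Wo;
    }
  }
  NumericVector out = alloc4(H, W, Cout, N);
  unpad_stack(Yp, H, W, Cout, N, b.begin(), out.begin());
  return out;
}

static List conv3_bwd(const NumericVector& x, const NumericVector& w,
                      const NumericVector& dy, int H, int W, int C, int N,
                      int Cout, bool want_dx) {
  const int Hp = H + 2, Wp = W + 2;
  const std::size_t P = (std::size_t)Hp * Wp;
  const int guard = Hp + 2;
  fmat Xp((std::size_t)P * N + 2 * guard, C);
  pad_stack(x.begin(), H, W, C, N, guard, Xp);
  fmat dYp((std::size_t)P * N + 2 * guard, Cout);
  pad_stack(dy.begin(), H, W, Cout, N, guard, dYp);
  fmat Wm = to_fmat(w, 9 * C, Cout);

  NumericVector dwv = alloc4(3, 3, C, Cout);
  NumericVector dbv(Cout);
  fmat dXp;
  if (want_dx) dXp.zeros((std::size_t)P * N, C);
  for (int j = 0; j < 3; ++j) {
    for (int i = 0; i < 3; ++i) {
      const long off = (i - 1) + Hp * (j - 1);
      // dW(tap) = X_shifted^T . dY  (padded dY rows are zero, so full rows
      // are exact)
      fmat dWo = Xp.rows(guard + off, guard + off + P * N - 1).t() *
                 dYp.rows(guard, guard + P * N - 1);
      for (int c = 0; c < C; ++c)
        for (int co = 0; co < Cout; ++co)
          dwv[(i + 3 * j + 9 * c) + 9 * C * co] = dWo(c, co);
      if (want_dx) {
        // dX gathers from dY at the opposite shift
        fmat Wo(C, Cout);
        for (int c = 0; c < C; ++c)
          for (int co = 0; co < Cout; ++co)
            Wo(c, co) = Wm(i + 3 * j + 9 * c, co);
        dXp += dYp.rows(guard - off, guard - off + P * N - 1) * Wo.t();
      }
    }
  }
  for (int co = 0; co < Cout; ++co) {
    const float* dc = dYp.colptr(co) + guard;
    double acc = 0.0;
    for (std::size_t q = 0; q < P * N; ++q) acc += dc[q];
    dbv[co] = acc;
  }
  NumericVector dxv;
  if (want_dx) {
    dxv = alloc4(H, W, C, N);
    unpad_stack(dXp, H, W, C, N, nullptr, dxv.begin());
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                  int stride, int pad, bool keep_cols) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (dw[1] != k) stop("kernel must be square");
  if (Cin != C) stop("conv channel mismatch: input has %d, weight expects %d", C, Cin);
  if (k == 3 && stride == 1 && pad == 1 && !keep_cols)
    return List::create(_["y"] = conv3_fwd(x, w, b, H, W, C, N, Cout));
  const int Ho = conv_out_dim(H, k, stride, pad);
  const int Wo = conv_out_dim(W, k, stride, pad);
  const int L = Ho * Wo, K = k * k * C;

  XPtr<fmat> colsPtr(new fmat((std::size_t)L * N, K), true);
  fmat& colsT = *colsPtr;
  for (int n = 0; n < N; ++n)
    im2colT_one(x.begin() + (std::size_t)H * W * C * n, H, W, C, k, stride,
                pad, colsT, (std::size_t)L * n);
  fmat Wm = to_fmat(w, K, Cout);
  fmat Y = colsT * Wm;  // (N*L) x Cout

  NumericVector out = alloc4(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    double* on = out.begin() + (std::size_t)L * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const float* src = Y.colptr(co) + (std::size_t)L * n;
      double* dst = on + (std::size_t)L * co;
      const double bc = b[co];
      for (int l = 0; l < L; ++l) dst[l] = (double)src[l] + bc;
    }
  }
  if (keep_cols) return List::create(_["y"] = out, _["cols"] = colsPtr);
  return List::create(_["y"] = out);
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, int pad, SEXP cols_cache, bool want_dx) {
  IntegerVector dx_ = dims4(x, "x"), dw_ = dims4(w, "w"), dy_ = dims4(dy, "dy");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int k = dw_[0], Cout = dw_[3];
  const int Ho = dy_[0], Wo = dy_[1];
  if (k == 3 && stride == 1 && pad == 1 && cols_cache == R_NilValue)
    return conv3_bwd(x, w, dy, H, W, C, N, Cout, want_dx);
  const int L = Ho * Wo, K = k * k * C;

  fmat* colsP;
  std::unique_ptr<fmat> own;
  if (cols_cache != R_NilValue) {
    colsP = XPtr<fmat>(cols_cache).get();
  } else {
    own.reset(new fmat((std::size_t)L * N, K));
    for (int n = 0; n < N; ++n)
      im2colT_one(x.begin() + (std::size_t)H * W * C * n, H, W, C, k, stride,
                  pad, *own, (std::size_t)L * n);
    colsP = own.get();
  }
  fmat& colsT = *colsP;
  fmat dYm = gather_LC(dy, L, Cout, N);
  fmat Wm = to_fmat(w, K, Cout);

  fmat dWm = colsT.t() * dYm;              // K x Cout
  arma::frowvec dBf = arma::sum(dYm, 0);   // Cout

  NumericVector dxv;
  if (want_dx) {
    fmat dcolsT = dYm * Wm.t();            // (N*L) x K
    dxv = alloc4(H, W, C, N);
    std::fill(dxv.begin(), dxv.end(), 0.0);
    for (int n = 0; n < N; ++n)
      col2imT_one(dcolsT, H, W, C, k, stride, pad,
                  dxv.begin() + (std::size_t)H * W * C * n, (std::size_t)L * n);
  }

  NumericVector dwv = alloc4(k, k, C, Cout);
  std::copy(dWm.begin(), dWm.end(), dwv.begin());
  NumericVector dbv(Cout);
  for (int co = 0; co < Cout; ++co) dbv[co] = dBf[co];
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Transposed convolution mapping Cin -> Cout channels; the weight is stored
// as the adjoint forward-conv weight (k, k, Cout, Cin), and the output
// spatial size is supplied explicitly (here always stride * input size).
// [[Rcpp::export]]
NumericVector cpp_convt_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad, int hout, int wout) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w");
  const int Hi = dx[0], Wi = dx[1], Ci = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[2], Cin = dw[3];
  if (Cin != Ci) stop("deconv channel mismatch: input has %d, weight expects %d", Ci, Cin);
  if (conv_out_dim(hout, k, stride, pad) != Hi ||
      conv_out_dim(wout, k, stride, pad) != Wi)
    stop("deconv output size inconsistent with input size");
  const int L = Hi * Wi, K = k * k * Cout;

  fmat Xm = gather_LC(x, L, Ci, N);
  fmat Wm = to_fmat(w, K, Ci);
  fmat dcolsT = Xm * Wm.t();  // (N*L) x K

  NumericVector out = alloc4(hout, wout, Cout, N);
  std::fill(out.begin(), out.end(), 0.0);
  const std::size_t plane = (std::size_t)hout * wout;
  for (int n = 0; n < N; ++n) {
    double* on = out.begin() + plane * Cout * n;
    col2imT_one(dcolsT, hout, wout, Cout, k, stride, pad, on,
                (std::size_t)L * n);
    for (int co = 0; co < Cout; ++co) {
      double* oc = on + plane * co;
      const double bc = b[co];
      for (std::size_t q = 0; q < plane; ++q) oc[q] += bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_convt_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad) {
  IntegerVector dx_ = dims4(x, "x"), dw_ = dims4(w, "w"), dy_ = dims4(dy, "dy");
  const int Hi = dx_[0], Wi = dx_[1], Ci = dx_[2], N = dx_[3];
  const int k = dw_[0], Cout = dw_[2];
  const int Ho = dy_[0], Wo = dy_[1];
  const int L = Hi * Wi, K = k * k * Cout;
  if (conv_out_dim(Ho, k, stride, pad) != Hi)
    stop("deconv gradient size inconsistent with input size");

  fmat colsT((std::size_t)L * N, K);
  const std::size_t plane = (std::size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    im2colT_one(dy.begin() + plane * Cout * n, Ho, Wo, Cout, k, stride, pad,
                colsT, (std::size_t)L * n);
  fmat Xm = gather_LC(x, L, Ci, N);
  fmat Wm = to_fmat(w, K, Ci);

  fmat dXm = colsT * Wm;         // (N*L) x Ci
  fmat dWm = colsT.t() * Xm;     // K x Ci

  NumericVector dxv = alloc4(Hi, Wi, Ci, N);
  for (int n = 0; n < N; ++n) {
    double* dn = dxv.begin() + (std::size_t)L * Ci * n;
    for (int c = 0; c < Ci; ++c) {
      const float* src = dXm.colptr(c) + (std::size_t)L * n;
      double* dst = dn + (std::size_t)L * c;
      for (int l = 0; l < L; ++l) dst[l] = (double)src[l];
    }
  }
  NumericVector dwv = alloc4(k, k, Cout, Ci);
  std::copy(dWm.begin(), dWm.end(), dwv.begin());
  NumericVector dbv(Cout);
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* dc = dy.begin() + plane * Cout * n + plane * co;
      for (std::size_t q = 0; q < plane; ++q) acc += dc[q];
    }
    dbv[co] = acc;
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Fused batch normalization + LeakyReLU forward. Batch statistics are the
// biased per-channel moments over (H, W, N). Returns the activation, the
// normalized input (needed for the backward pass; skipped when want_cache
// is false), the inverse standard deviations and the updated running
// moments. All statistics in double.
// [[Rcpp::export]]
List cpp_bn_act_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                    NumericVector rmean, NumericVector rvar, bool training,
                    double momentum, double eps, double slope,
                    bool want_cache) {
  IntegerVector d = dims4(x, "x");
  const int Hh = d[0], Ww = d[1], C = d[2], N = d[3];
  const std::size_t plane = (std::size_t)Hh * Ww;
  const std::size_t M = plane * N;

  NumericVector mean(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + plane * (c + (std::size_t)C * n);
        for (std::size_t q = 0; q < plane; ++q) {
          const double v = xc[q];
          s += v; s2 += v * v;
        }
      }
      mean[c] = s / M;
      var[c] = s2 / M - mean[c] * mean[c];
      if (var[c] < 0) var[c] = 0;
    }
  } else {
    for (int c = 0; c < C; ++c) { mean[c] = rmean[c]; var[c] = rvar[c]; }
  }

  NumericVector y = alloc4(Hh, Ww, C, N);
  NumericVector xhat;
  if (want_cache) xhat = alloc4(Hh, Ww, C, N);
  NumericVector invstd(C);
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(var[c] + eps);
    invstd[c] = is;
    const double g = gamma[c], bt = beta[c], mu = mean[c];
    for (int n = 0; n < N; ++n) {
      const std::size_t off = plane * (c + (std::size_t)C * n);
      const double* xc = x.begin() + off;
      double* yc = y.begin() + off;
      double* hc = want_cache ? xhat.begin() + off : nullptr;
      for (std::size_t q = 0; q < plane; ++q) {
        const double h = (xc[q] - mu) * is;
        if (hc) hc[q] = h;
        const double a = g * h + bt;
        yc[q] = a >= 0 ? a : slope * a;
      }
    }
  }
  NumericVector rm(C), rv(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      rm[c] = (1 - momentum) * rmean[c] + momentum * mean[c];
      rv[c] = (1 - momentum) * rvar[c] + momentum * var[c];
    }
  } else {
    rm = clone(rmean); rv = clone(rvar);
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rmean"] = rm, _["rvar"] = rv);
}

// Backward of the fused op. The LeakyReLU mask is recovered from the sign
// of the forward output (slope > 0 preserves sign).
// [[Rcpp::export]]
List cpp_bn_act_bwd(NumericVector dy, NumericVector y, NumericVector xhat,
                    NumericVector invstd, NumericVector gamma, double slope) {
  IntegerVector d = dims4(dy, "dy");
  const int Hh = d[0], Ww = d[1], C = d[2], N = d[3];
  const std::size_t plane = (std::size_t)Hh * Ww;
  const std::size_t M = plane * N;

  NumericVector dx = alloc4(Hh, Ww, C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], is = invstd[c];
    double s_da = 0.0, s_dah = 0.0;
    for (int n = 0; n < N; ++n) {
      const std::size_t off = plane * (c + (std::size_t)C * n);
      const double* dyc = dy.begin() + off;
      const double* yc = y.begin() + off;
      const double* hc = xhat.begin() + off;
      for (std::size_t q = 0; q < plane; ++q) {
        const double da = yc[q] >= 0 ? dyc[q] : slope * dyc[q];
        s_da += da;
        s_dah += da * hc[q];
      }
    }
    dbeta[c] = s_da;
    dgamma[c] = s_dah;
    const double m1 = g * s_da / M;
    const double m2 = g * s_dah / M;
    for (int n = 0; n < N; ++n) {
      const std::size_t off = plane * (c + (std::size_t)C * n);
      const double* dyc = dy.begin() + off;
      const double* yc = y.begin() + off;
      const double* hc = xhat.begin() + off;
      double* dxc = dx.begin() + off;
      for (std::size_t q = 0; q < plane; ++q) {
        const double da = yc[q] >= 0 ? dyc[q] : slope * dyc[q];
        dxc[q] = is * (g * da - m1 - hc[q] * m2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
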