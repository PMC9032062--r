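// Low-level neural-network kernels: same-padding 2-D convolution, valid
// max-pooling, per-channel batch normalization (optionally fused with a
// leaky rectifier), and dropout. Tensors cross the R boundary as double
// arrays in (H = time, W = electrode, C, N) column-major layout.
//
// Convolution strategy: the kernel is factored over its electrode-axis
// offsets. A per-sample im2col over TIME offsets only (P x kh*Cin, built in
// float) serves every electrode offset through shifted row views, so each
// (sample, electrode-offset) is one large single-precision GEMM and the
// column matrix is kw times smaller than a full im2col. This keeps the
// arithmetic BLAS-bound while touching little memory -- important because
// large fresh allocations are far more expensive than FLOPs here.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

static inline void get_dim4(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// float copy of sample n of x: (P x Cin), P = H*W
static void sample_to_float(const double* xn, size_t len, float* dst) {
  for (size_t i = 0; i < len; ++i) dst[i] = (float)xn[i];
}

// col(p = (h, w), k = (dh, ci)) = xf(h + dh - ph, w, ci), zero outside.
static void im2col_time(const arma::fmat& xf, int H, int W, int Cin,
                        int kh, arma::fmat& col) {
  const int ph = (kh - 1) / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    const float* xc = xf.colptr(ci);
    for (int dh = 0; dh < kh; ++dh) {
      float* dst = col.colptr(dh + kh * ci);
      const int sh = dh - ph;                 // source shift along time
      for (int w = 0; w < W; ++w) {
        float* d = dst + (size_t)w * H;
        const float* s = xc + (size_t)w * H;
        int h0 = std::max(0, -sh), h1 = std::min(H, H - sh);
        for (int h = 0; h < h0; ++h) d[h] = 0.0f;
        if (h1 > h0) std::memcpy(d + h0, s + h0 + sh, sizeof(float) * (h1 - h0));
        for (int h = h1; h < H; ++h) d[h] = 0.0f;
      }
    }
  }
}

// scatter-add of dcol back into dxf (the transpose of im2col_time)
static void col2im_time(const arma::fmat& dcol, int H, int W, int Cin,
                        int kh, arma::fmat& dxf) {
  const int ph = (kh - 1) / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    float* xc = dxf.colptr(ci);
    for (int dh = 0; dh < kh; ++dh) {
      const float* src = dcol.colptr(dh + kh * ci);
      const int sh = dh - ph;
      for (int w = 0; w < W; ++w) {
        float* d = xc + (size_t)w * H;
        const float* s = src + (size_t)w * H;
        int h0 = std::max(0, -sh), h1 = std::min(H, H - sh);
        for (int h = h0; h < h1; ++h) d[h + sh] += s[h];
      }
    }
  }
}

// weights as kw slices of (kh*Cin x Cout)
static arma::fcube weights_to_slices(const NumericVector& w, int kh, int kw,
                                     int Cin, int Cout) {
  arma::fcube wf(kh * Cin, Cout, kw);
  // w element (dh, dw, ci, co) at dh + kh*(dw + kw*(ci + Cin*co))
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dw = 0; dw < kw; ++dw)
        for (int dh = 0; dh < kh; ++dh)
          wf(dh + kh * ci, co, dw) =
            (float)w[dh + (size_t)kh * (dw + (size_t)kw * (ci + (size_t)Cin * co))];
  return wf;
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int xd[4]; get_dim4(x, xd);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[2] != xd[2]) stop("weight/input channel mismatch");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int P = H * W, pw = (kw - 1) / 2;
  arma::fcube wf = weights_to_slices(w, kh, kw, Cin, Cout);
  NumericVector y(no_init((size_t)P * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::fmat xf(P, Cin), col(P, kh * Cin), yn(P, Cout);
  for (int n = 0; n < N; ++n) {
    sample_to_float(&x[(size_t)n * P * Cin], (size_t)P * Cin, xf.memptr());
    im2col_time(xf, H, W, Cin, kh, col);
    yn.zeros();
    for (int dw = 0; dw < kw; ++dw) {
      int wlo = std::max(0, pw - dw), whi = std::min(W, W + pw - dw);
      if (whi <= wlo) continue;
      yn.rows((size_t)wlo * H, (size_t)whi * H - 1) +=
        col.rows((size_t)(wlo + dw - pw) * H, (size_t)(whi + dw - pw) * H - 1) *
        wf.slice(dw);
    }
    double* yp = &y[(size_t)n * P * Cout];
    for (int co = 0; co < Cout; ++co) {
      const float* s = yn.colptr(co);
      const double bb = b[co];
      double* d = yp + (size_t)co * P;
      for (int p = 0; p < P; ++p) d[p] = (double)s[p] + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   bool need_dx) {
  int xd[4]; get_dim4(x, xd);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int P = H * W, pw = (kw - 1) / 2;
  arma::fcube wf = weights_to_slices(w, kh, kw, Cin, Cout);
  arma::fcube dwf(kh * Cin, Cout, kw, arma::fill::zeros);
  NumericVector db(Cout);
  NumericVector dx(need_dx ? (R_xlen_t)x.size() : 0);
  if (need_dx) dx.attr("dim") = x.attr("dim");
  arma::fmat xf(P, Cin), col(P, kh * Cin), dyn(P, Cout);
  arma::fmat dcol, dxf;
  if (need_dx) { dcol.set_size(P, kh * Cin); dxf.set_size(P, Cin); }
  for (int n = 0; n < N; ++n) {
    const double* dyp = &dy[(size_t)n * P * Cout];
    for (int co = 0; co < Cout; ++co) {
      float* d = dyn.colptr(co);
      const double* s = dyp + (size_t)co * P;
      double acc = 0.0;
      for (int p = 0; p < P; ++p) { d[p] = (float)s[p]; acc += s[p]; }
      db[co] += acc;
    }
    sample_to_float(&x[(size_t)n * P * Cin], (size_t)P * Cin, xf.memptr());
    im2col_time(xf, H, W, Cin, kh, col);
    if (need_dx) dcol.zeros();
    for (int dw = 0; dw < kw; ++dw) {
      int wlo = std::max(0, pw - dw), whi = std::min(W, W + pw - dw);
      if (whi <= wlo) continue;
      size_t r0 = (size_t)(wlo + dw - pw) * H, r1 = (size_t)(whi + dw - pw) * H - 1;
      size_t y0 = (size_t)wlo * H, y1 = (size_t)whi * H - 1;
      dwf.slice(dw) += col.rows(r0, r1).t() * dyn.rows(y0, y1);
      if (need_dx)
        dcol.rows(r0, r1) += dyn.rows(y0, y1) * wf.slice(dw).t();
    }
    if (need_dx) {
      dxf.zeros();
      col2im_time(dcol, H, W, Cin, kh, dxf);
      double* dxp = &dx[(size_t)n * P * Cin];
      const float* s = dxf.memptr();
      for (size_t i = 0; i < (size_t)P * Cin; ++i) dxp[i] = (double)s[i];
    }
  }
  NumericVector dw_out(no_init(w.size()));
  dw_out.attr("dim") = w.attr("dim");
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dwi = 0; dwi < kw; ++dwi)
        for (int dh = 0; dh < kh; ++dh)
          dw_out[dh + (size_t)kh * (dwi + (size_t)kw * (ci + (size_t)Cin * co))] =
            (double)dwf(dh + kh * ci, co, dwi);
  return List::create(_["dx"] = dx, _["dw"] = dw_out, _["db"] = db);
}

// [[Rcpp::export]]
List nn_maxpool_fwd(NumericVector x, int kh, int kw, int sh, int sw) {
  int xd[4]; get_dim4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H - kh) / sh + 1, Wo = (W - kw) / sw + 1;
  if (Ho < 1 || Wo < 1) stop("input too small for pooling window");
  NumericVector y(no_init((size_t)Ho * Wo * C * N));
  IntegerVector idx(no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = &x[(size_t)(n * C + c) * H * W];
      size_t o = (size_t)(n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; int bi = 0;
          for (int dw = 0; dw < kw; ++dw)
            for (int dh = 0; dh < kh; ++dh) {
              int i = (ho * sh + dh) + H * (wo * sw + dw);
              if (xs[i] > best) { best = xs[i]; bi = i; }
            }
          size_t oo = o + ho + (size_t)Ho * wo;
          y[oo] = best;
          idx[oo] = (int)((size_t)(n * C + c) * H * W) + bi;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(IntegerVector idx, NumericVector dy,
                             IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// Batch normalization over (H, W, N) per channel; when alpha >= 0, a leaky
// rectifier with that negative slope is fused onto the output.
// [[Rcpp::export]]
List nn_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
               double eps, double alpha) {
  int xd[4]; get_dim4(x, xd);
  const int C = xd[2], N = xd[3];
  const size_t plane = (size_t)xd[0] * xd[1];
  const double m = (double)plane * N;
  NumericVector mean(C), var(C), y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xs = &x[((size_t)n * C + c) * plane];
      for (size_t i = 0; i < plane; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
    }
    double mu = s / m, v = s2 / m - mu * mu;
    if (v < 0) v = 0;
    mean[c] = mu; var[c] = v;
    double inv = 1.0 / std::sqrt(v + eps);
    double a = gamma[c] * inv, bb = beta[c] - mu * a;
    for (int n = 0; n < N; ++n) {
      const double* xs = &x[((size_t)n * C + c) * plane];
      double* ys = &y[((size_t)n * C + c) * plane];
      if (alpha >= 0)
        for (size_t i = 0; i < plane; ++i) {
          double z = a * xs[i] + bb;
          ys[i] = z > 0 ? z : alpha * z;
        }
      else
        for (size_t i = 0; i < plane; ++i) ys[i] = a * xs[i] + bb;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// Inference-mode normalization with fixed statistics (same fused rectifier).
// [[Rcpp::export]]
NumericVector nn_bn_infer(NumericVector x, NumericVector gamma,
                          NumericVector beta, NumericVector mean,
                          NumericVector var, double eps, double alpha) {
  int xd[4]; get_dim4(x, xd);
  const int C = xd[2], N = xd[3];
  const size_t plane = (size_t)xd[0] * xd[1];
  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double a = gamma[c] * inv, bb = beta[c] - mean[c] * a;
    for (int n = 0; n < N; ++n) {
      const double* xs = &x[((size_t)n * C + c) * plane];
      double* ys = &y[((size_t)n * C + c) * plane];
      if (alpha >= 0)
        for (size_t i = 0; i < plane; ++i) {
          double z = a * xs[i] + bb;
          ys[i] = z > 0 ? z : alpha * z;
        }
      else
        for (size_t i = 0; i < plane; ++i) ys[i] = a * xs[i] + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
               NumericVector beta, NumericVector mean, NumericVector var,
               double eps, double alpha) {
  int xd[4]; get_dim4(x, xd);
  const int C = xd[2], N = xd[3];
  const size_t plane = (size_t)xd[0] * xd[1];
  const double m = (double)plane * N;
  NumericVector dx(no_init(x.size())), dgamma(C), dbeta(C);
  dx.attr("dim") = x.attr("dim");
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double a = gamma[c] * inv, bb = beta[c] - mean[c] * a;
    double sum_dy = 0, sum_dy_xhat = 0;
    // first pass: fold the rectifier into dy and accumulate reductions
    for (int n = 0; n < N; ++n) {
      const double* xs = &x[((size_t)n * C + c) * plane];
      const double* ds = &dy[((size_t)n * C + c) * plane];
      for (size_t i = 0; i < plane; ++i) {
        double d = ds[i];
        if (alpha >= 0 && a * xs[i] + bb <= 0) d *= alpha;
        double xh = (xs[i] - mean[c]) * inv;
        sum_dy += d;
        sum_dy_xhat += d * xh;
      }
    }
    dbeta[c] = sum_dy;
    dgamma[c] = sum_dy_xhat;
    for (int n = 0; n < N; ++n) {
      const double* xs = &x[((size_t)n * C + c) * plane];
      const double* ds = &dy[((size_t)n * C + c) * plane];
      double* dd = &dx[((size_t)n * C + c) * plane];
      for (size_t i = 0; i < plane; ++i) {
        double d = ds[i];
        if (alpha >= 0 && a * xs[i] + bb <= 0) d *= alpha;
        double xh = (xs[i] - mean[c]) * inv;
        dd[i] = gamma[c] * inv * (d - sum_dy / m - xh * sum_dy_xhat / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector nn_leaky_fwd(NumericVector x, double alpha) {
  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* xs = REAL(x);
  double* ys = REAL(y);
  for (R_xlen_t i = 0; i < x.size(); ++i)
    ys[i] = xs[i] > 0 ? xs[i] : alpha * xs[i];
  return y;
}

// [[Rcpp::export]]
NumericVector nn_leaky_bwd(NumericVector x, NumericVector dy, double alpha) {
  NumericVector dx(no_init(x.size()));
  dx.attr("dim") = x.attr("dim");
  const double* xs = REAL(x);
  const double* ds = REAL(dy);
  double* dd = REAL(dx);
  for (R_xlen_t i = 0; i < x.size(); ++i)
    dd[i] = xs[i] > 0 ? ds[i] : alpha * ds[i];
  return dx;
}

// Inverted dropout, applied IN PLACE on x (the caller owns x and must not
// share it); deterministic given `seed`. Returns the keep-mask.
// [[Rcpp::export]]
RawVector nn_dropout_fwd(NumericVector x, double rate, int seed) {
  RawVector mask(no_init(x.size()));
  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double scale = 1.0 / (1.0 - rate);
  double* xs = REAL(x);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (unif(rng) >= rate) { mask[i] = 1; xs[i] *= scale; }
    else { mask[i] = 0; xs[i] = 0.0; }
  }
  return mask;
}

// [[Rcpp::export]]
NumericVector nn_dropout_bwd(RawVector mask, NumericVector dy, double rate) {
  NumericVector dx(no_init(dy.size()));
  dx.attr("dim") = dy.attr("dim");
  const double scale = 1.0 / (1.0 - rate);
  const double* ds = REAL(dy);
  double* dd = REAL(dx);
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dd[i] = mask[i] ? ds[i] * scale : 0.0;
  return dx;
}
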