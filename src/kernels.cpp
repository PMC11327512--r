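// Numerical kernels for the change-detection network and the spectral
// front end. Tensors cross the R/C++ boundary as column-major numeric
// arrays with dim (H, W, C, N); convolution weights as (Cout x K)
// matrices with K = (Cin/groups)*kh*kw, row index cg*kh*kw + kj*kh + ki.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col_group(const double* xp, int H, int W, int C, int n,
                                int g, int Cg, int kh, int kw, int stride,
                                int pad, int Ho, int Wo, arma::mat& col) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      int p = oh + Ho * ow;
      int ih0 = oh * stride - pad, iw0 = ow * stride - pad;
      for (int cg = 0; cg < Cg; ++cg) {
        int c = g * Cg + cg;
        const double* xc = xp + ((size_t)n * C + c) * (size_t)H * W;
        for (int kj = 0; kj < kw; ++kj) {
          int iw = iw0 + kj;
          for (int ki = 0; ki < kh; ++ki) {
            int ih = ih0 + ki;
            col(cg * kh * kw + kj * kh + ki, p) =
                (ih >= 0 && ih < H && iw >= 0 && iw < W)
                    ? xc[ih + (size_t)H * iw]
                    : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, const arma::mat& W,
                          const arma::vec& b, int kh, int kw, int stride,
                          int pad, int groups) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  int Cout = W.n_rows;
  int Cg = C / groups, CoutG = Cout / groups;
  int K = Cg * kh * kw;
  if ((int)W.n_cols != K) stop("weight shape does not match kernel/groups");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (Wd + 2 * pad - kw) / stride + 1;
  size_t P = (size_t)Ho * Wo;
  NumericVector y((size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0 &&
                    groups == 1);
  if (pointwise) {
    // 1x1 convolution: channel planes are contiguous, so each sample is a
    // plain (P x C) * (C x Cout) GEMM on memory views, no im2col copy
    for (int n = 0; n < N; ++n) {
      const arma::mat X(const_cast<double*>(xp) + (size_t)n * P * C, P, C,
                        false, true);
      arma::mat Y(yp + (size_t)n * P * Cout, P, Cout, false, true);
      Y = X * W.t();
      Y.each_row() += arma::conv_to<arma::rowvec>::from(b);
    }
    return y;
  }
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col_group(xp, H, Wd, C, n, g, Cg, kh, kw, stride, pad, Ho, Wo, col);
      arma::mat yg = W.rows(g * CoutG, (g + 1) * CoutG - 1) * col;
      for (int co = 0; co < CoutG; ++co) {
        int c = g * CoutG + co;
        double* yc = yp + ((size_t)n * Cout + c) * P;
        double bc = b[c];
        for (size_t p = 0; p < P; ++p) yc[p] = yg(co, p) + bc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x, const arma::mat& W, NumericVector dy,
                 int kh, int kw, int stride, int pad, int groups,
                 bool need_dx) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  int Cout = W.n_rows;
  int Cg = C / groups, CoutG = Cout / groups;
  int K = Cg * kh * kw;
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (Wd + 2 * pad - kw) / stride + 1;
  size_t P = (size_t)Ho * Wo;
  NumericVector dx((size_t)H * Wd * C * N);
  dx.attr("dim") = xd;
  arma::mat dW(Cout, K, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0 && groups == 1) {
    arma::vec db1(Cout, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      const arma::mat X(const_cast<double*>(xp) + (size_t)n * P * C, P, C,
                        false, true);
      const arma::mat dY(const_cast<double*>(dyp) + (size_t)n * P * Cout, P,
                         Cout, false, true);
      dW += dY.t() * X;
      db1 += arma::sum(dY, 0).t();
      if (need_dx) {
        arma::mat dX(dxp + (size_t)n * P * C, P, C, false, true);
        dX = dY * W;
      }
    }
    return List::create(Named("dx") = dx, Named("dW") = dW,
                        Named("db") = db1);
  }
  arma::mat col(K, P), dyg(CoutG, P);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col_group(xp, H, Wd, C, n, g, Cg, kh, kw, stride, pad, Ho, Wo, col);
      for (int co = 0; co < CoutG; ++co) {
        int c = g * CoutG + co;
        const double* dyc = dyp + ((size_t)n * Cout + c) * P;
        for (size_t p = 0; p < P; ++p) dyg(co, p) = dyc[p];
      }
      dW.rows(g * CoutG, (g + 1) * CoutG - 1) += dyg * col.t();
      db.subvec(g * CoutG, (g + 1) * CoutG - 1) += arma::sum(dyg, 1);
      if (!need_dx) continue;
      arma::mat dcol = W.rows(g * CoutG, (g + 1) * CoutG - 1).t() * dyg;
      // col2im: scatter-add dcol back to input positions
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          int p = oh + Ho * ow;
          int ih0 = oh * stride - pad, iw0 = ow * stride - pad;
          for (int cg = 0; cg < Cg; ++cg) {
            int c = g * Cg + cg;
            double* dxc = dxp + ((size_t)n * C + c) * (size_t)H * Wd;
            for (int kj = 0; kj < kw; ++kj) {
              int iw = iw0 + kj;
              if (iw < 0 || iw >= Wd) continue;
              for (int ki = 0; ki < kh; ++ki) {
                int ih = ih0 + ki;
                if (ih < 0 || ih >= H) continue;
                dxc[ih + (size_t)H * iw] += dcol(cg * kh * kw + kj * kh + ki, p);
              }
            }
          }
        }
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dW") = dW, Named("db") = db);
}

// Centered short-time Fourier power: optional first-order pre-emphasis
// (y[t] = x[t] - alpha x[t-1]), reflect padding by n_fft/2 on each side,
// frames starting at t*hop in the padded signal, n_frames = 1 +
// floor(n/hop). Real frames are packed two-per-complex-FFT and unpacked
// by Hermitian symmetry.
// [[Rcpp::export]]
arma::mat stft_power(const arma::vec& wave, int n_fft, int hop,
                     const arma::vec& window, double preemph = 0.0) {
  int n = wave.n_elem;
  int half = n_fft / 2;
  if (n <= half) stop("waveform too short for centered framing");
  arma::vec x(n);
  x[0] = wave[0];
  for (int i = 1; i < n; ++i) x[i] = wave[i] - preemph * wave[i - 1];
  arma::vec padded(n + 2 * half);
  for (int i = 0; i < n; ++i) padded[half + i] = x[i];
  for (int i = 0; i < half; ++i) {
    padded[half - 1 - i] = x[i + 1];
    padded[half + n + i] = x[n - 2 - i];
  }
  int n_frames = 1 + n / hop;
  int nb = n_fft / 2 + 1;
  int n_pair = (n_frames + 1) / 2;
  arma::cx_mat packed(n_fft, n_pair);
  for (int tp = 0; tp < n_pair; ++tp) {
    int t0 = 2 * tp, t1 = 2 * tp + 1;
    int s0 = t0 * hop, s1 = t1 * hop;
    if (t1 < n_frames) {
      for (int i = 0; i < n_fft; ++i)
        packed(i, tp) = std::complex<double>(padded[s0 + i] * window[i],
                                             padded[s1 + i] * window[i]);
    } else {
      for (int i = 0; i < n_fft; ++i)
        packed(i, tp) = std::complex<double>(padded[s0 + i] * window[i], 0.0);
    }
  }
  arma::cx_mat spec = arma::fft(packed);
  arma::mat S(nb, n_frames);
  for (int tp = 0; tp < n_pair; ++tp) {
    int t0 = 2 * tp, t1 = 2 * tp + 1;
    for (int k = 0; k < nb; ++k) {
      int kc = (n_fft - k) % n_fft;
      std::complex<double> zk = spec(k, tp), zc = std::conj(spec(kc, tp));
      std::complex<double> a = 0.5 * (zk + zc);           // frame t0
      std::complex<double> bd = 0.5 * (zk - zc);          // i * frame t1
      S(k, t0) = std::norm(a);
      if (t1 < n_frames) S(k, t1) = std::norm(bd);
    }
  }
  return S;
}

// Batch normalization over (H, W, N) per channel on (H, W, C, N) arrays.
// Returns y plus the cached normalized input and inverse std needed for
// the backward pass. In training mode running statistics are updated in
// the returned rmean/rvar copies (unbiased variance, torch convention).
// [[Rcpp::export]]
List nn_bn_fwd(NumericVector x, const arma::vec& gamma, const arma::vec& beta,
               const arma::vec& rmean, const arma::vec& rvar, double momentum,
               double eps, bool train, bool act) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  arma::vec mu(C), var(C), inv(C);
  arma::vec rm = rmean, rv = rvar;
  double cnt = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    if (train) {
      for (int n = 0; n < N; ++n) {
        const double* xc = xp + ((size_t)n * C + c) * HW;
        for (size_t i = 0; i < HW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      mu[c] = s / cnt;
      var[c] = s2 / cnt - mu[c] * mu[c];
      if (var[c] < 0) var[c] = 0;
      rm[c] = (1 - momentum) * rm[c] + momentum * mu[c];
      rv[c] = (1 - momentum) * rv[c] +
              momentum * var[c] * cnt / std::max(1.0, cnt - 1);
    } else {
      mu[c] = rmean[c];
      var[c] = rvar[c];
    }
    inv[c] = 1.0 / std::sqrt(var[c] + eps);
    double g = gamma[c], b = beta[c], m = mu[c], iv = inv[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = xp + ((size_t)n * C + c) * HW;
      double* yc = yp + ((size_t)n * C + c) * HW;
      double* hc = hp + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        double h = (xc[i] - m) * iv;
        hc[i] = h;
        double v = g * h + b;
        yc[i] = (act && v < 0) ? 0.0 : v;
      }
    }
  }
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("inv") = inv, Named("rmean") = rm,
                      Named("rvar") = rv);
}

// [[Rcpp::export]]
List nn_bn_bwd(NumericVector xhat, const arma::vec& inv,
               const arma::vec& gamma, NumericVector dy, NumericVector y,
               bool act) {
  IntegerVector xd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  NumericVector dx(dy.size());
  dx.attr("dim") = xd;
  const double* hp = xhat.begin();
  const double* dp = dy.begin();
  const double* yp2 = y.begin();
  double* op = dx.begin();
  arma::vec dgamma(C), dbeta(C);
  double cnt = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double sd = 0, sdh = 0;
    for (int n = 0; n < N; ++n) {
      const double* hc = hp + ((size_t)n * C + c) * HW;
      const double* dc = dp + ((size_t)n * C + c) * HW;
      const double* yc = yp2 + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        double d = (act && yc[i] <= 0) ? 0.0 : dc[i];
        sd += d; sdh += d * hc[i];
      }
    }
    dgamma[c] = sdh;
    dbeta[c] = sd;
    double g = gamma[c], iv = inv[c];
    double md = sd / cnt, mdh = sdh / cnt;
    for (int n = 0; n < N; ++n) {
      const double* hc = hp + ((size_t)n * C + c) * HW;
      const double* dc = dp + ((size_t)n * C + c) * HW;
      const double* yc = yp2 + ((size_t)n * C + c) * HW;
      double* oc = op + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        double d = (act && yc[i] <= 0) ? 0.0 : dc[i];
        oc[i] = g * iv * (d - md - hc[i] * mdh);
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
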