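// Low-level numeric kernels for the 3D convolutional models.
//
// Volumes are stored as R arrays with dim (D, H, W, C, N): spatial index
// fastest within a channel, channels within a sample, samples last.
// Convolution weights have dim (kd, kh, kw, Cin, Cout); transposed
// convolution weights have dim (kd, kh, kw, Cout, Cin).
//
// Convolutions are lowered to GEMM through an im2col buffer laid out as a
// (positions x kernel-rows) matrix so that the innermost im2col loop writes
// contiguously. GEMM runs in single precision through Armadillo/BLAS; the
// R-facing interface stays double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Dims5 { int d, h, w, c, n; };

Dims5 dims5(const NumericVector& x, const char* what) {
  SEXP da = x.attr("dim");
  if (Rf_isNull(da)) stop("'%s' must be a 5-d array", what);
  IntegerVector dm(da);
  if (dm.size() != 5) stop("'%s' must be a 5-d array", what);
  Dims5 out = {dm[0], dm[1], dm[2], dm[3], dm[4]};
  return out;
}

inline int conv_out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

void to_float(const double* src, size_t n, float* dst) {
  for (size_t i = 0; i < n; ++i) dst[i] = static_cast<float>(src[i]);
}

} // namespace

// floor division (C++ '/' truncates toward zero)
static inline int fdiv(int a, int b) {
  int q = a / b;
  if (a % b != 0 && (a < 0) != (b < 0)) --q;
  return q;
}

// Gather the patches of one sample into the rows of colT.
// colT element (pos, r) lives at colT[row0 + pos + ld * r]. The sample's
// image has spatial-fastest layout with channel stride `chstride` from
// `sample_base` (chstride = D*H*W for packed samples).
void im2col_g(const float* sample_base, size_t chstride,
              int D, int H, int W, int C,
              int kd, int kh, int kw, int s, int p,
              int OD, int OH, int OW,
              float* colT, size_t row0, size_t ld)
{
  const int K3 = kd * kh * kw;
  const size_t DH = (size_t)D * H;
  for (int c = 0; c < C; ++c) {
    const float* im = sample_base + (size_t)c * chstride;
    for (int l = 0; l < kw; ++l)
      for (int j = 0; j < kh; ++j)
        for (int i = 0; i < kd; ++i) {
          const int r = i + kd * (j + kh * l) + K3 * c;
          float* dst = colT + row0 + ld * (size_t)r;
          // od range with in-bounds source index id = od*s - p + i
          const int o0 = std::min(OD, std::max(0, fdiv(p - i + s - 1, s)));
          const int o1 = std::max(o0, std::min(OD, fdiv(D - 1 + p - i, s) + 1));
          for (int ow = 0; ow < OW; ++ow) {
            const int iw = ow * s - p + l;
            const bool wok = iw >= 0 && iw < W;
            for (int oh = 0; oh < OH; ++oh) {
              const int ih = oh * s - p + j;
              float* d2 = dst + (size_t)OD * (oh + (size_t)OH * ow);
              if (!wok || ih < 0 || ih >= H) {
                std::fill(d2, d2 + OD, 0.0f);
                continue;
              }
              const float* base = im + (size_t)ih * D + (size_t)iw * DH;
              for (int od = 0; od < o0; ++od) d2[od] = 0.0f;
              const float* sp = base + (o0 * s - p + i);
              for (int od = o0; od < o1; ++od, sp += s) d2[od] = *sp;
              for (int od = o1; od < OD; ++od) d2[od] = 0.0f;
            }
          }
        }
  }
}

// Adjoint of im2col_g: accumulate the rows of colT back into an image.
void col2im_g(const float* colT, size_t row0, size_t ld,
              int D, int H, int W, int C, size_t chstride,
              int kd, int kh, int kw, int s, int p,
              int OD, int OH, int OW, float* sample_base)
{
  const int K3 = kd * kh * kw;
  const size_t DH = (size_t)D * H;
  for (int c = 0; c < C; ++c) {
    float* im = sample_base + (size_t)c * chstride;
    for (int l = 0; l < kw; ++l)
      for (int j = 0; j < kh; ++j)
        for (int i = 0; i < kd; ++i) {
          const int r = i + kd * (j + kh * l) + K3 * c;
          const float* srcr = colT + row0 + ld * (size_t)r;
          const int o0 = std::min(OD, std::max(0, fdiv(p - i + s - 1, s)));
          const int o1 = std::max(o0, std::min(OD, fdiv(D - 1 + p - i, s) + 1));
          for (int ow = 0; ow < OW; ++ow) {
            const int iw = ow * s - p + l;
            if (iw < 0 || iw >= W) continue;
            for (int oh = 0; oh < OH; ++oh) {
              const int ih = oh * s - p + j;
              if (ih < 0 || ih >= H) continue;
              const float* s2 = srcr + (size_t)OD * (oh + (size_t)OH * ow);
              float* base = im + (size_t)ih * D + (size_t)iw * DH;
              float* bp = base + (o0 * s - p + i);
              for (int od = o0; od < o1; ++od, bp += s) *bp += s2[od];
            }
          }
        }
  }
}

namespace {

// Build the (P*N x K3*Cin) patch matrix for a whole batch stored as an R
// array (D,H,W,C,N).
arma::fmat batch_im2col(const NumericVector& x, const Dims5& xd,
                        int kd, int kh, int kw, int s, int p,
                        int OD, int OH, int OW)
{
  const size_t P = (size_t)OD * OH * OW, PN = P * xd.n;
  const size_t R = (size_t)kd * kh * kw * xd.c;
  const size_t samp = (size_t)xd.d * xd.h * xd.w * xd.c;
  const size_t DHW = (size_t)xd.d * xd.h * xd.w;
  arma::fmat colT(PN, R);
  std::vector<float> xf(samp);
  const double* xp = REAL(x);
  for (int n = 0; n < xd.n; ++n) {
    to_float(xp + (size_t)n * samp, samp, xf.data());
    im2col_g(xf.data(), DHW, xd.d, xd.h, xd.w, xd.c, kd, kh, kw, s, p,
             OD, OH, OW, colT.memptr(), (size_t)n * P, PN);
  }
  return colT;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad)
{
  Dims5 xd = dims5(x, "x"), wd = dims5(w, "w");
  if (wd.c != xd.c) stop("input channels (%d) do not match weight channels (%d)", xd.c, wd.c);
  const int OD = conv_out_dim(xd.d, wd.d, stride, pad);
  const int OH = conv_out_dim(xd.h, wd.h, stride, pad);
  const int OW = conv_out_dim(xd.w, wd.w, stride, pad);
  if (OD < 1 || OH < 1 || OW < 1) stop("convolution output would be empty");
  const int Cout = wd.n, N = xd.n;
  const size_t P = (size_t)OD * OH * OW;
  const size_t R = (size_t)wd.d * wd.h * wd.w * xd.c;

  arma::fmat colT = batch_im2col(x, xd, wd.d, wd.h, wd.w, stride, pad, OD, OH, OW);
  arma::fmat Wm(R, Cout);
  to_float(REAL(w), R * (size_t)Cout, Wm.memptr());
  arma::fmat Y = colT * Wm;   // (P*N) x Cout

  NumericVector out((R_xlen_t)(P * Cout * N));
  double* op = REAL(out);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const float* yc = Y.colptr(co) + (size_t)n * P;
      const double bb = b[co];
      double* dst = op + ((size_t)n * Cout + co) * P;
      for (size_t q = 0; q < P; ++q) dst[q] = (double)yc[q] + bb;
    }
  out.attr("dim") = IntegerVector::create(OD, OH, OW, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, bool need_dx)
{
  Dims5 xd = dims5(x, "x"), wd = dims5(w, "w"), yd = dims5(dy, "dy");
  const int Cout = wd.n, N = xd.n;
  const size_t P = (size_t)yd.d * yd.h * yd.w;
  const size_t PN = P * N;
  const size_t R = (size_t)wd.d * wd.h * wd.w * xd.c;

  arma::fmat colT = batch_im2col(x, xd, wd.d, wd.h, wd.w, stride, pad,
                                 yd.d, yd.h, yd.w);
  // gather dY into (P*N) x Cout
  arma::fmat dY(PN, Cout);
  const double* dp = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      float* dst = dY.colptr(co) + (size_t)n * P;
      const double* src = dp + ((size_t)n * Cout + co) * P;
      for (size_t q = 0; q < P; ++q) dst[q] = (float)src[q];
    }

  arma::fmat dW = colT.t() * dY;          // R x Cout
  arma::frowvec db = arma::sum(dY, 0);

  NumericVector dwv(dW.n_elem);
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, REAL(dwv));
  dwv.attr("dim") = IntegerVector::create(wd.d, wd.h, wd.w, wd.c, wd.n);
  NumericVector dbv(Cout);
  for (int co = 0; co < Cout; ++co) dbv[co] = db[co];

  NumericVector dxv;
  if (need_dx) {
    arma::fmat Wm(R, Cout);
    to_float(REAL(w), R * (size_t)Cout, Wm.memptr());
    arma::fmat dcolT = dY * Wm.t();       // (P*N) x R
    const size_t samp = (size_t)xd.d * xd.h * xd.w * xd.c;
    dxv = NumericVector((R_xlen_t)(samp * N));
    std::vector<float> buf(samp);
    for (int n = 0; n < N; ++n) {
      std::fill(buf.begin(), buf.end(), 0.0f);
      col2im_g(dcolT.memptr(), (size_t)n * P, PN,
               xd.d, xd.h, xd.w, xd.c, (size_t)xd.d * xd.h * xd.w,
               wd.d, wd.h, wd.w, stride, pad,
               yd.d, yd.h, yd.w, buf.data());
      double* dst = REAL(dxv) + (size_t)n * samp;
      for (size_t q = 0; q < samp; ++q) dst[q] = buf[q];
    }
    dxv.attr("dim") = IntegerVector::create(xd.d, xd.h, xd.w, xd.c, xd.n);
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
NumericVector cpp_convt3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                              int stride, int pad)
{
  Dims5 xd = dims5(x, "x"), wd = dims5(w, "w");   // wd: kd,kh,kw,Cout,Cin
  const int Cout = wd.c, Cin = wd.n, N = xd.n;
  if (Cin != xd.c) stop("input channels (%d) do not match weight channels (%d)", xd.c, Cin);
  const int OD = (xd.d - 1) * stride - 2 * pad + wd.d;
  const int OH = (xd.h - 1) * stride - 2 * pad + wd.h;
  const int OW = (xd.w - 1) * stride - 2 * pad + wd.w;
  if (OD < 1 || OH < 1 || OW < 1) stop("transposed convolution output would be empty");
  const size_t Pin = (size_t)xd.d * xd.h * xd.w, PN = Pin * N;
  const size_t R = (size_t)wd.d * wd.h * wd.w * Cout;

  arma::fmat Xall(PN, Cin);
  const double* xp = REAL(x);
  for (int n = 0; n < N; ++n)
    for (int ci = 0; ci < Cin; ++ci) {
      float* dst = Xall.colptr(ci) + (size_t)n * Pin;
      const double* src = xp + ((size_t)n * Cin + ci) * Pin;
      for (size_t q = 0; q < Pin; ++q) dst[q] = (float)src[q];
    }
  arma::fmat Wt(R, Cin);
  to_float(REAL(w), R * (size_t)Cin, Wt.memptr());
  arma::fmat colT = Xall * Wt.t();   // (Pin*N) x R

  const size_t samp_out = (size_t)OD * OH * OW * Cout;
  NumericVector out((R_xlen_t)(samp_out * N));
  std::vector<float> buf(samp_out);
  for (int n = 0; n < N; ++n) {
    std::fill(buf.begin(), buf.end(), 0.0f);
    col2im_g(colT.memptr(), (size_t)n * Pin, PN,
             OD, OH, OW, Cout, (size_t)OD * OH * OW,
             wd.d, wd.h, wd.w, stride, pad,
             xd.d, xd.h, xd.w, buf.data());
    double* dst = REAL(out) + (size_t)n * samp_out;
    const size_t PO = (size_t)OD * OH * OW;
    for (int co = 0; co < Cout; ++co) {
      const double bb = b[co];
      const float* src = buf.data() + (size_t)co * PO;
      double* d2 = dst + (size_t)co * PO;
      for (size_t q = 0; q < PO; ++q) d2[q] = (double)src[q] + bb;
    }
  }
  out.attr("dim") = IntegerVector::create(OD, OH, OW, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_convt3d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad)
{
  Dims5 xd = dims5(x, "x"), wd = dims5(w, "w"), yd = dims5(dy, "dy");
  const int Cout = wd.c, Cin = wd.n, N = xd.n;
  const size_t Pin = (size_t)xd.d * xd.h * xd.w, PN = Pin * N;
  const size_t R = (size_t)wd.d * wd.h * wd.w * Cout;

  // patches of the upstream gradient, with the output grid as the image
  arma::fmat colT = batch_im2col(dy, yd, wd.d, wd.h, wd.w, stride, pad,
                                 xd.d, xd.h, xd.w);
  arma::fmat Wt(R, Cin);
  to_float(REAL(w), R * (size_t)Cin, Wt.memptr());

  arma::fmat Xall(PN, Cin);
  const double* xp = REAL(x);
  for (int n = 0; n < N; ++n)
    for (int ci = 0; ci < Cin; ++ci) {
      float* dst = Xall.colptr(ci) + (size_t)n * Pin;
      const double* src = xp + ((size_t)n * Cin + ci) * Pin;
      for (size_t q = 0; q < Pin; ++q) dst[q] = (float)src[q];
    }

  arma::fmat dX = colT * Wt;          // (Pin*N) x Cin
  arma::fmat dW = colT.t() * Xall;    // R x Cin

  NumericVector dxv((R_xlen_t)(Pin * Cin * N));
  for (int n = 0; n < N; ++n)
    for (int ci = 0; ci < Cin; ++ci) {
      const float* src = dX.colptr(ci) + (size_t)n * Pin;
      double* dst = REAL(dxv) + ((size_t)n * Cin + ci) * Pin;
      for (size_t q = 0; q < Pin; ++q) dst[q] = src[q];
    }
  dxv.attr("dim") = IntegerVector::create(xd.d, xd.h, xd.w, xd.c, xd.n);

  NumericVector dwv(dW.n_elem);
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, REAL(dwv));
  dwv.attr("dim") = IntegerVector::create(wd.d, wd.h, wd.w, wd.c, wd.n);

  NumericVector dbv(Cout);
  const size_t PO = (size_t)yd.d * yd.h * yd.w;
  const double* dp = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = dp + ((size_t)n * Cout + co) * PO;
      double s = 0.0;
      for (size_t q = 0; q < PO; ++q) s += src[q];
      dbv[co] += s;
    }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List cpp_bn3d_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                  NumericVector rmean, NumericVector rvar,
                  double eps, double momentum, bool training)
{
  Dims5 xd = dims5(x, "x");
  const size_t P = (size_t)xd.d * xd.h * xd.w;
  const int C = xd.c, N = xd.n;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  NumericVector mu(C), var(C), rm = clone(rmean), rv = clone(rvar);
  const double m = (double)P * N;
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    double mc, vc;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p0 = xp + ((size_t)n * C + c) * P;
        for (size_t i = 0; i < P; ++i) { s += p0[i]; s2 += p0[i] * p0[i]; }
      }
      mc = s / m;
      vc = s2 / m - mc * mc;
      if (vc < 0) vc = 0;
      rm[c] = (1 - momentum) * rm[c] + momentum * mc;
      rv[c] = (1 - momentum) * rv[c] + momentum * (m > 1 ? vc * m / (m - 1) : vc);
    } else {
      mc = rmean[c];
      vc = rvar[c];
    }
    mu[c] = mc; var[c] = vc;
    const double inv = 1.0 / std::sqrt(vc + eps);
    const double g = gamma[c] * inv, shift = beta[c] - gamma[c] * inv * mc;
    for (int n = 0; n < N; ++n) {
      const double* p0 = xp + ((size_t)n * C + c) * P;
      double* q0 = yp + ((size_t)n * C + c) * P;
      for (size_t i = 0; i < P; ++i) q0[i] = g * p0[i] + shift;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = var,
                      _["running_mean"] = rm, _["running_var"] = rv);
}

// [[Rcpp::export]]
List cpp_bn3d_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
                  NumericVector mean, NumericVector var, double eps,
                  bool training)
{
  Dims5 xd = dims5(x, "x");
  const size_t P = (size_t)xd.d * xd.h * xd.w;
  const int C = xd.c, N = xd.n;
  const double m = (double)P * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  const double* dp = REAL(dy);
  double* op = REAL(dx);
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps), mc = mean[c];
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* x0 = xp + ((size_t)n * C + c) * P;
      const double* d0 = dp + ((size_t)n * C + c) * P;
      for (size_t i = 0; i < P; ++i) {
        sdy += d0[i];
        sdyx += d0[i] * (x0[i] - mc) * inv;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double g = gamma[c] * inv;
    if (training) {
      for (int n = 0; n < N; ++n) {
        const double* x0 = xp + ((size_t)n * C + c) * P;
        const double* d0 = dp + ((size_t)n * C + c) * P;
        double* o0 = op + ((size_t)n * C + c) * P;
        for (size_t i = 0; i < P; ++i) {
          const double xhat = (x0[i] - mc) * inv;
          o0[i] = g * (d0[i] - sdy / m - xhat * sdyx / m);
        }
      }
    } else {
      for (int n = 0; n < N; ++n) {
        const double* d0 = dp + ((size_t)n * C + c) * P;
        double* o0 = op + ((size_t)n * C + c) * P;
        for (size_t i = 0; i < P; ++i) o0[i] = g * d0[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_fwd(NumericVector x, double slope)
{
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bwd(NumericVector x, NumericVector dy, double slope)
{
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  const double* dp = REAL(dy);
  double* op = REAL(dx);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? dp[i] : slope * dp[i];
  return dx;
}
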