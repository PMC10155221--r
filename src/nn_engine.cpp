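// Fused single-precision training/inference engine for the 3D conv models.
//
// The granular operators in nn_ops.cpp are the reference implementation
// (double in/out, used by the unit tests and small-scale paths). Training
// runs through the fused steps below: one call performs the full forward
// and backward pass of a minibatch in single precision with persistent
// workspaces, and returns the loss, parameter gradients and updated
// batch-norm running statistics to R, where the (double-precision) Adam
// update lives. A test asserts that the fused step reproduces the
// reference path's loss and gradients.
//
// Activation layout: each layer's batch activation is a (P*N x C) float
// matrix, column c holding channel c for all positions of all samples
// (sample n occupies rows [n*P, (n+1)*P)). This makes batch-norm a
// column-wise operation and convolution a single GEMM against an im2col
// patch matrix. Batch norm and leaky ReLU are fused into single passes,
// and all large buffers persist across calls (R is single-threaded).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// generalized patch gather/scatter shared with nn_ops.cpp
void im2col_g(const float* sample_base, size_t chstride,
              int D, int H, int W, int C,
              int kd, int kh, int kw, int s, int p,
              int OD, int OH, int OW,
              float* colT, size_t row0, size_t ld);
void col2im_g(const float* colT, size_t row0, size_t ld,
              int D, int H, int W, int C, size_t chstride,
              int kd, int kh, int kw, int s, int p,
              int OD, int OH, int OW, float* sample_base);

extern "C" void sgemm_(const char* ta, const char* tb,
                       const int* m, const int* n, const int* k,
                       const float* alpha, const float* A, const int* lda,
                       const float* B, const int* ldb,
                       const float* beta, float* C, const int* ldc);

namespace {

const double BN_EPS = 1e-5, BN_MOM = 0.1;

// C = op(A) * op(B), reusing C's memory when the size is unchanged
void gemm_f(arma::fmat& C, const arma::fmat& A, bool tA,
            const arma::fmat& B, bool tB) {
  const int m = tA ? A.n_cols : A.n_rows;
  const int k = tA ? A.n_rows : A.n_cols;
  const int n = tB ? B.n_rows : B.n_cols;
  C.set_size(m, n);
  const float one = 1.0f, zero = 0.0f;
  const int lda = A.n_rows, ldb = B.n_rows, ldc = m;
  sgemm_(tA ? "T" : "N", tB ? "T" : "N", &m, &n, &k, &one,
         A.memptr(), &lda, B.memptr(), &ldb, &zero, C.memptr(), &ldc);
}

struct Shape3 { int d, h, w; int prod() const { return d * h * w; } };

struct BlockP {
  arma::fmat W;          // (K3*Cin x Cout) for conv, (K3*Cout x Cin) for convT
  arma::fvec b, gamma, beta, rmean, rvar;
  int kd, kh, kw, cin, cout;
  bool has_bn;
  IntegerVector wdim;
};

BlockP load_block(List blk, bool transposed) {
  BlockP p;
  NumericVector w = blk["W"];
  p.wdim = w.attr("dim");
  p.kd = p.wdim[0]; p.kh = p.wdim[1]; p.kw = p.wdim[2];
  if (transposed) { p.cout = p.wdim[3]; p.cin = p.wdim[4]; }
  else { p.cin = p.wdim[3]; p.cout = p.wdim[4]; }
  const int K3 = p.kd * p.kh * p.kw;
  const int nrow = transposed ? K3 * p.cout : K3 * p.cin;
  const int ncol = transposed ? p.cin : p.cout;
  p.W.set_size(nrow, ncol);
  std::copy(w.begin(), w.end(), p.W.memptr());
  NumericVector b = blk["b"];
  p.b = arma::conv_to<arma::fvec>::from(as<arma::vec>(b));
  p.has_bn = blk.containsElementNamed("gamma") && !Rf_isNull(blk["gamma"]);
  if (p.has_bn) {
    p.gamma = arma::conv_to<arma::fvec>::from(as<arma::vec>(NumericVector(blk["gamma"])));
    p.beta = arma::conv_to<arma::fvec>::from(as<arma::vec>(NumericVector(blk["beta"])));
    p.rmean = arma::conv_to<arma::fvec>::from(as<arma::vec>(NumericVector(blk["rmean"])));
    p.rvar = arma::conv_to<arma::fvec>::from(as<arma::vec>(NumericVector(blk["rvar"])));
  }
  return p;
}

std::vector<BlockP> load_blocks(List lst, bool transposed) {
  std::vector<BlockP> out;
  for (int i = 0; i < lst.size(); ++i) out.push_back(load_block(lst[i], transposed));
  return out;
}

NumericVector fmat_to_r(const arma::fmat& m, IntegerVector dim) {
  NumericVector out(m.n_elem);
  std::copy(m.memptr(), m.memptr() + m.n_elem, REAL(out));
  out.attr("dim") = dim;
  return out;
}

NumericVector fvec_to_r(const arma::fvec& v) {
  NumericVector out(v.n_elem);
  std::copy(v.memptr(), v.memptr() + v.n_elem, REAL(out));
  return out;
}

struct BnStats { arma::fvec mean, var; };

// sum and sum-of-squares with unrolled accumulator lanes (fixed order,
// deterministic; the unroll only breaks the FP dependency chain)
inline void sum_sq8(const float* x, size_t n, double& s_out, double& s2_out) {
  double s[4] = {0, 0, 0, 0}, s2[4] = {0, 0, 0, 0};
  size_t i = 0;
  for (; i + 4 <= n; i += 4) {
    for (int l = 0; l < 4; ++l) {
      const double v = x[i + l];
      s[l] += v; s2[l] += v * v;
    }
  }
  for (; i < n; ++i) { const double v = x[i]; s[0] += v; s2[0] += v * v; }
  s_out = (s[0] + s[1]) + (s[2] + s[3]);
  s2_out = (s2[0] + s2[1]) + (s2[2] + s2[3]);
}

// conv output (+ bias) -> batch norm -> leaky ReLU in one pass.
// conv holds the raw GEMM output (no bias); act receives the block output.
// In training mode batch stats are computed (bias cancels in the mean) and
// running stats are updated inside blk.
void block_act_fwd(const arma::fmat& conv, arma::fmat& act, BlockP& blk,
                   BnStats& st, bool bn_train, float slope) {
  const int C = conv.n_cols;
  const size_t rows = conv.n_rows;
  const double cnt = (double)rows;
  act.set_size(rows, C);
  st.mean.set_size(C); st.var.set_size(C);
  for (int c = 0; c < C; ++c) {
    const float* xp = conv.colptr(c);
    const double bias = blk.b[c];
    double mc, vc;
    if (bn_train) {
      double s, s2;
      sum_sq8(xp, rows, s, s2);
      const double m0 = s / cnt;
      mc = m0 + bias;                       // mean of conv + bias
      vc = s2 / cnt - m0 * m0;              // bias shifts, variance unchanged
      if (vc < 0) vc = 0;
      blk.rmean[c] = (float)((1 - BN_MOM) * blk.rmean[c] + BN_MOM * mc);
      blk.rvar[c] = (float)((1 - BN_MOM) * blk.rvar[c] +
                            BN_MOM * (cnt > 1 ? vc * cnt / (cnt - 1) : vc));
    } else {
      mc = blk.rmean[c];
      vc = blk.rvar[c];
    }
    st.mean[c] = (float)mc; st.var[c] = (float)vc;
    const float g = (float)(blk.gamma[c] / std::sqrt(vc + BN_EPS));
    const float shift = (float)(blk.beta[c] + g * (bias - mc));
    float* ap = act.colptr(c);
    for (size_t i = 0; i < rows; ++i) {
      const float y = g * xp[i] + shift;
      ap[i] = y > 0 ? y : slope * y;
    }
  }
}

// backward through leaky ReLU + batch norm in two passes.
// On entry d holds the gradient at the block output; on exit it holds the
// gradient at the conv output. act is the block output (sign carries the
// leaky-ReLU derivative); conv the raw GEMM output (bias cancels in xhat).
void block_act_bwd(const arma::fmat& conv, const arma::fmat& act,
                   arma::fmat& d, const BlockP& blk, const BnStats& st,
                   bool bn_train, float slope,
                   arma::fvec& dgamma, arma::fvec& dbeta) {
  const int C = conv.n_cols;
  const size_t rows = conv.n_rows;
  const double cnt = (double)rows;
  dgamma.set_size(C); dbeta.set_size(C);
  for (int c = 0; c < C; ++c) {
    const float* xp = conv.colptr(c);
    const float* ap = act.colptr(c);
    float* dp = d.colptr(c);
    const double inv = 1.0 / std::sqrt((double)st.var[c] + BN_EPS);
    const double mu = (double)st.mean[c] - blk.b[c];  // mean of raw conv
    double sdy, sdyx;
    {
      double a0[4] = {0, 0, 0, 0}, a1[4] = {0, 0, 0, 0};
      size_t i = 0;
      for (; i + 4 <= rows; i += 4) {
        for (int l = 0; l < 4; ++l) {
          const float dyv = ap[i + l] > 0 ? dp[i + l] : slope * dp[i + l];
          dp[i + l] = dyv;
          a0[l] += dyv;
          a1[l] += dyv * ((double)xp[i + l] - mu);
        }
      }
      for (; i < rows; ++i) {
        const float dyv = ap[i] > 0 ? dp[i] : slope * dp[i];
        dp[i] = dyv;
        a0[0] += dyv;
        a1[0] += dyv * ((double)xp[i] - mu);
      }
      sdy = (a0[0] + a0[1]) + (a0[2] + a0[3]);
      sdyx = ((a1[0] + a1[1]) + (a1[2] + a1[3])) * inv;
    }
    dgamma[c] = (float)sdyx; dbeta[c] = (float)sdy;
    const double g = blk.gamma[c] * inv;
    if (bn_train) {
      const double a = sdy / cnt, bq = sdyx / cnt;
      for (size_t i = 0; i < rows; ++i) {
        const double xhat = ((double)xp[i] - mu) * inv;
        dp[i] = (float)(g * ((double)dp[i] - a - xhat * bq));
      }
    } else {
      for (size_t i = 0; i < rows; ++i) dp[i] = (float)(g * dp[i]);
    }
  }
}

struct LayerCache {
  arma::fmat conv;   // raw conv GEMM output, no bias (decoder final block:
                     // output activation values instead)
  arma::fmat act;    // post-activation block output
  arma::fmat colT;   // patch matrix of the layer input (training only)
  BnStats st;
  Shape3 in_shape, out_shape;
};

void batch_im2col_mat(const arma::fmat& act, Shape3 sh, int N,
                      const BlockP& blk, int s, int p, Shape3 osh,
                      arma::fmat& colT) {
  const size_t P = sh.prod(), PN = act.n_rows;
  const size_t PO = osh.prod(), PON = PO * N;
  const int K3 = blk.kd * blk.kh * blk.kw;
  colT.set_size(PON, (size_t)K3 * act.n_cols);
  for (int n = 0; n < N; ++n) {
    im2col_g(act.memptr() + (size_t)n * P, PN,
             sh.d, sh.h, sh.w, act.n_cols,
             blk.kd, blk.kh, blk.kw, s, p, osh.d, osh.h, osh.w,
             colT.memptr(), (size_t)n * PO, PON);
  }
}

Shape3 conv_oshape(Shape3 sh, const BlockP& blk, int s, int p) {
  return Shape3{(sh.d + 2 * p - blk.kd) / s + 1,
                (sh.h + 2 * p - blk.kh) / s + 1,
                (sh.w + 2 * p - blk.kw) / s + 1};
}

// ---- encoder ----

void encoder_fwd(std::vector<BlockP>& blocks, std::vector<LayerCache>& cache,
                 Shape3 in_shape, int N, int s, int p,
                 float slope, bool training, int frozen, int upto,
                 bool keep) {
  // cache[0].act must already hold the input
  if ((int)cache.size() < upto + 1) cache.resize(upto + 1);
  cache[0].out_shape = in_shape;
  for (int i = 0; i < upto; ++i) {
    BlockP& blk = blocks[i];
    Shape3 sh = cache[i].out_shape;
    Shape3 osh = conv_oshape(sh, blk, s, p);
    LayerCache& L = cache[i + 1];
    L.in_shape = sh; L.out_shape = osh;
    batch_im2col_mat(cache[i].act, sh, N, blk, s, p, osh, L.colT);
    gemm_f(L.conv, L.colT, false, blk.W, false);
    const bool bn_train = training && (i + 1) > frozen;
    block_act_fwd(L.conv, L.act, blk, L.st, bn_train, slope);
    if (!keep) { L.conv.reset(); L.colT.reset(); }
  }
}

void encoder_bwd(std::vector<BlockP>& blocks, std::vector<LayerCache>& cache,
                 int N, int s, int p, float slope, int frozen, int n_layers,
                 arma::fmat& d,
                 std::vector<arma::fmat>& dW, std::vector<arma::fvec>& db,
                 std::vector<arma::fvec>& dgamma, std::vector<arma::fvec>& dbeta,
                 std::vector<bool>& have, arma::fmat& dcolT) {
  dW.resize(n_layers); db.resize(n_layers);
  dgamma.resize(n_layers); dbeta.resize(n_layers);
  have.assign(n_layers, false);
  for (int i = n_layers; i >= 1; --i) {
    if (i <= frozen) break;
    BlockP& blk = blocks[i - 1];
    LayerCache& L = cache[i];
    block_act_bwd(L.conv, L.act, d, blk, L.st, true, slope,
                  dgamma[i - 1], dbeta[i - 1]);
    gemm_f(dW[i - 1], L.colT, true, d, false);
    db[i - 1] = arma::sum(d, 0).t();
    have[i - 1] = true;
    const bool need_dx = (i - 1) >= 1 && (i - 1) > frozen;
    if (!need_dx) break;
    gemm_f(dcolT, d, false, blk.W, true);
    const size_t Pl = (size_t)L.in_shape.prod();
    d.zeros(Pl * N, blk.cin);
    const size_t PO = L.out_shape.prod(), PON = PO * (size_t)N;
    for (int n = 0; n < N; ++n) {
      col2im_g(dcolT.memptr(), (size_t)n * PO, PON,
               L.in_shape.d, L.in_shape.h, L.in_shape.w, blk.cin, Pl * N,
               blk.kd, blk.kh, blk.kw, s, p,
               L.out_shape.d, L.out_shape.h, L.out_shape.w,
               d.memptr() + (size_t)n * Pl);
    }
  }
}

// ---- decoder ----

void decoder_fwd(std::vector<BlockP>& blocks, std::vector<LayerCache>& cache,
                 const arma::fmat& z, Shape3 z_shape, int N, int s, int p,
                 float slope, bool training, int out_act, bool keep) {
  const int n_layers = blocks.size();
  if ((int)cache.size() < n_layers + 1) cache.resize(n_layers + 1);
  cache[0].act = z;
  cache[0].out_shape = z_shape;
  for (int i = 0; i < n_layers; ++i) {
    BlockP& blk = blocks[i];
    Shape3 sh = cache[i].out_shape;
    Shape3 osh{(sh.d - 1) * s - 2 * p + blk.kd,
               (sh.h - 1) * s - 2 * p + blk.kh,
               (sh.w - 1) * s - 2 * p + blk.kw};
    LayerCache& L = cache[i + 1];
    L.in_shape = sh; L.out_shape = osh;
    const size_t PO = osh.prod(), PON = PO * (size_t)N;
    const size_t Pin = sh.prod();
    // patch matrix of the output, directly in (positions x rows) layout
    gemm_f(L.colT, cache[i].act, false, blk.W, true);
    L.conv.zeros(PON, blk.cout);
    for (int n = 0; n < N; ++n) {
      col2im_g(L.colT.memptr(), (size_t)n * Pin, L.colT.n_rows,
               osh.d, osh.h, osh.w, blk.cout, PON,
               blk.kd, blk.kh, blk.kw, s, p, sh.d, sh.h, sh.w,
               L.conv.memptr() + (size_t)n * PO);
    }
    if (i < n_layers - 1) {
      block_act_fwd(L.conv, L.act, blk, L.st, training, slope);
    } else {
      L.act.set_size(PON, blk.cout);
      const float* cp = L.conv.memptr();
      float* ap = L.act.memptr();
      const float bias = blk.b[0];
      if (out_act == 0)
        for (size_t q = 0; q < L.act.n_elem; ++q) ap[q] = std::tanh(cp[q] + bias);
      else
        for (size_t q = 0; q < L.act.n_elem; ++q) ap[q] = 1.0f / (1.0f + std::exp(-(cp[q] + bias)));
    }
    if (!keep) { L.conv.reset(); L.colT.reset(); }
  }
}

void decoder_bwd(std::vector<BlockP>& blocks, std::vector<LayerCache>& cache,
                 int N, int s, int p, float slope, int out_act,
                 arma::fmat& d,
                 std::vector<arma::fmat>& dW, std::vector<arma::fvec>& db,
                 std::vector<arma::fvec>& dgamma, std::vector<arma::fvec>& dbeta,
                 arma::fmat& colT) {
  const int n_layers = blocks.size();
  dW.resize(n_layers); db.resize(n_layers);
  dgamma.resize(n_layers); dbeta.resize(n_layers);
  arma::fmat dnew;
  for (int i = n_layers; i >= 1; --i) {
    BlockP& blk = blocks[i - 1];
    LayerCache& L = cache[i];
    if (i == n_layers) {
      const float* ap = L.act.memptr();
      float* dp = d.memptr();
      if (out_act == 0)
        for (size_t q = 0; q < d.n_elem; ++q) dp[q] *= 1.0f - ap[q] * ap[q];
      else
        for (size_t q = 0; q < d.n_elem; ++q) dp[q] *= ap[q] * (1.0f - ap[q]);
    } else {
      block_act_bwd(L.conv, L.act, d, blk, L.st, true, slope,
                    dgamma[i - 1], dbeta[i - 1]);
    }
    db[i - 1] = arma::sum(d, 0).t();
    batch_im2col_mat(d, L.out_shape, N, blk, s, p, L.in_shape, colT);
    gemm_f(dW[i - 1], colT, true, cache[i - 1].act, false); // (K3*Cout x Cin)
    gemm_f(dnew, colT, false, blk.W, false);                // (Pin*N x Cin)
    d = std::move(dnew);
  }
}

// Gather samples `idx` (1-based; empty = all) of a (D,H,W,1,N) array into
// a float column.
void load_input(NumericVector x, IntegerVector idx, arma::fmat& dst,
                int& D, int& H, int& W, int& N) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 5) stop("expected a 5-d array");
  D = dm[0]; H = dm[1]; W = dm[2];
  if (dm[3] != 1) stop("expected a single input channel");
  const size_t P = (size_t)D * H * W;
  const double* xp = REAL(x);
  N = idx.size() > 0 ? idx.size() : dm[4];
  dst.set_size(P * N, 1);
  float* op = dst.memptr();
  for (int n = 0; n < N; ++n) {
    const int src_n = idx.size() > 0 ? idx[n] - 1 : n;
    if (src_n < 0 || src_n >= dm[4]) stop("sample index out of range");
    const double* sp = xp + (size_t)src_n * P;
    float* dp = op + (size_t)n * P;
    for (size_t q = 0; q < P; ++q) dp[q] = (float)sp[q];
  }
}

List pack_enc_grads(const std::vector<arma::fmat>& dW,
                    const std::vector<arma::fvec>& db,
                    const std::vector<arma::fvec>& dgamma,
                    const std::vector<arma::fvec>& dbeta,
                    const std::vector<bool>& have,
                    const std::vector<BlockP>& blocks) {
  List out(dW.size());
  for (size_t i = 0; i < dW.size(); ++i) {
    if (!have[i]) { out[i] = R_NilValue; continue; }
    out[i] = List::create(
      _["W"] = fmat_to_r(dW[i], blocks[i].wdim),
      _["b"] = fvec_to_r(db[i]),
      _["gamma"] = fvec_to_r(dgamma[i]),
      _["beta"] = fvec_to_r(dbeta[i]));
  }
  return out;
}

List pack_running(const std::vector<BlockP>& blocks, int frozen) {
  List out(blocks.size());
  for (size_t i = 0; i < blocks.size(); ++i) {
    if (!blocks[i].has_bn || (int)(i + 1) <= frozen) {
      out[i] = R_NilValue;
    } else {
      out[i] = List::create(_["rmean"] = fvec_to_r(blocks[i].rmean),
                            _["rvar"] = fvec_to_r(blocks[i].rvar));
    }
  }
  return out;
}

// ---- full training loops -------------------------------------------------
//
// Double-precision master parameters and Adam state live here for the
// whole run; each step converts to float, runs the fused forward/backward,
// and applies the update. Only the final parameters and the per-epoch loss
// cross the R boundary, which removes all per-step marshalling overhead.

struct MasterBlock {
  std::vector<double> W, b, gamma, beta, rmean, rvar;
  IntegerVector wdim;
  bool has_bn;
};

std::vector<double> as_dvec(SEXP x) {
  NumericVector v(x);
  return std::vector<double>(v.begin(), v.end());
}

MasterBlock load_master(List blk) {
  MasterBlock m;
  NumericVector w = blk["W"];
  m.wdim = w.attr("dim");
  m.W = as_dvec(blk["W"]);
  m.b = as_dvec(blk["b"]);
  m.has_bn = blk.containsElementNamed("gamma") && !Rf_isNull(blk["gamma"]);
  if (m.has_bn) {
    m.gamma = as_dvec(blk["gamma"]);
    m.beta = as_dvec(blk["beta"]);
    m.rmean = as_dvec(blk["rmean"]);
    m.rvar = as_dvec(blk["rvar"]);
  }
  return m;
}

std::vector<MasterBlock> load_masters(List lst) {
  std::vector<MasterBlock> out;
  for (int i = 0; i < lst.size(); ++i) out.push_back(load_master(lst[i]));
  return out;
}

// rebuild the BlockP float view of a master block
BlockP master_view(const MasterBlock& m, bool transposed) {
  BlockP p;
  p.wdim = m.wdim;
  p.kd = m.wdim[0]; p.kh = m.wdim[1]; p.kw = m.wdim[2];
  if (transposed) { p.cout = m.wdim[3]; p.cin = m.wdim[4]; }
  else { p.cin = m.wdim[3]; p.cout = m.wdim[4]; }
  const int K3 = p.kd * p.kh * p.kw;
  const int nrow = transposed ? K3 * p.cout : K3 * p.cin;
  const int ncol = transposed ? p.cin : p.cout;
  p.W.set_size(nrow, ncol);
  for (size_t i = 0; i < m.W.size(); ++i) p.W.memptr()[i] = (float)m.W[i];
  p.b.set_size(m.b.size());
  for (size_t i = 0; i < m.b.size(); ++i) p.b[i] = (float)m.b[i];
  p.has_bn = m.has_bn;
  if (m.has_bn) {
    p.gamma.set_size(m.gamma.size());
    p.beta.set_size(m.beta.size());
    p.rmean.set_size(m.rmean.size());
    p.rvar.set_size(m.rvar.size());
    for (size_t i = 0; i < m.gamma.size(); ++i) {
      p.gamma[i] = (float)m.gamma[i]; p.beta[i] = (float)m.beta[i];
      p.rmean[i] = (float)m.rmean[i]; p.rvar[i] = (float)m.rvar[i];
    }
  }
  return p;
}

struct AdamBuf { std::vector<double> m, v; };

void adam_apply(std::vector<double>& p, const float* g, AdamBuf& st,
                double lr, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  if (st.m.empty()) { st.m.assign(p.size(), 0.0); st.v.assign(p.size(), 0.0); }
  const double c1 = 1.0 - std::pow(b1, (double)t);
  const double c2 = 1.0 - std::pow(b2, (double)t);
  for (size_t i = 0; i < p.size(); ++i) {
    const double gi = g[i];
    st.m[i] = b1 * st.m[i] + (1 - b1) * gi;
    st.v[i] = b2 * st.v[i] + (1 - b2) * gi * gi;
    p[i] -= lr * (st.m[i] / c1) / (std::sqrt(st.v[i] / c2) + eps);
  }
}

NumericVector dvec_to_r(const std::vector<double>& v, SEXP dim = R_NilValue) {
  NumericVector out(v.begin(), v.end());
  if (!Rf_isNull(dim)) out.attr("dim") = dim;
  return out;
}

// rebuild the R parameter blocks with the same field layout alloc_block()
// uses, so trained and freshly built models are structurally identical
List masters_to_r(const std::vector<MasterBlock>& ms, bool transposed) {
  List out(ms.size());
  for (size_t i = 0; i < ms.size(); ++i) {
    const MasterBlock& m = ms[i];
    if (m.has_bn) {
      out[i] = List::create(_["W"] = dvec_to_r(m.W, m.wdim),
                            _["b"] = dvec_to_r(m.b),
                            _["transposed"] = transposed,
                            _["gamma"] = dvec_to_r(m.gamma),
                            _["beta"] = dvec_to_r(m.beta),
                            _["rmean"] = dvec_to_r(m.rmean),
                            _["rvar"] = dvec_to_r(m.rvar));
    } else {
      out[i] = List::create(_["W"] = dvec_to_r(m.W, m.wdim),
                            _["b"] = dvec_to_r(m.b),
                            _["transposed"] = transposed);
    }
  }
  return out;
}

void fold_bn_back(MasterBlock& m, const BlockP& p) {
  if (!m.has_bn) return;
  for (size_t i = 0; i < m.rmean.size(); ++i) {
    m.rmean[i] = p.rmean[i];
    m.rvar[i] = p.rvar[i];
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_cnn_train(NumericVector x, IntegerVector y, List enc, List dense,
                   int frozen, double slope, int stride, int pad,
                   double lr, int batch_size, List orders)
{
  IntegerVector dm = x.attr("dim");
  const int n_total = dm[4];
  std::vector<MasterBlock> masters = load_masters(enc);
  const int n_layers = masters.size();
  std::vector<double> Wd = as_dvec(dense["W"]);
  std::vector<double> bd = as_dvec(dense["b"]);
  NumericMatrix Wd_r = dense["W"];
  const int latent = Wd_r.nrow(), K = Wd_r.ncol();

  std::vector<AdamBuf> stW(n_layers), stB(n_layers), stG(n_layers), stBt(n_layers);
  AdamBuf stWd, stBd;
  long t = 0;
  const int n_epochs = orders.size();
  NumericVector history(n_epochs);

  std::vector<LayerCache> cache(1);
  for (int e = 0; e < n_epochs; ++e) {
    IntegerVector ord = orders[e];
    double ep_loss = 0.0;
    for (int start = 0; start < ord.size(); start += batch_size) {
      const int len = std::min((int)ord.size() - start, batch_size);
      IntegerVector idx(len);
      for (int q = 0; q < len; ++q) idx[q] = ord[start + q];

      std::vector<BlockP> blocks;
      for (int i = 0; i < n_layers; ++i)
        blocks.push_back(master_view(masters[i], false));

      int D, H, W, N;
      load_input(x, idx, cache[0].act, D, H, W, N);
      encoder_fwd(blocks, cache, Shape3{D, H, W}, N, stride, pad,
                  (float)slope, true, frozen, n_layers, true);

      LayerCache& top = cache[n_layers];
      const size_t P = top.out_shape.prod();
      const int C = top.act.n_cols;
      arma::fmat Z((size_t)latent, N);
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < C; ++c)
          std::copy(top.act.colptr(c) + (size_t)n * P,
                    top.act.colptr(c) + (size_t)n * P + P,
                    Z.colptr(n) + (size_t)c * P);
      arma::fmat Wdf((size_t)latent, K);
      for (size_t i = 0; i < Wd.size(); ++i) Wdf.memptr()[i] = (float)Wd[i];
      arma::fvec bdf(K);
      for (int i = 0; i < K; ++i) bdf[i] = (float)bd[i];

      arma::fmat logits;
      gemm_f(logits, Wdf, true, Z, false);
      logits.each_col() += bdf;
      double loss = 0;
      arma::fmat probs = logits;
      for (int n = 0; n < N; ++n) {
        float mx = probs.col(n).max();
        double sum = 0;
        float* pp = probs.colptr(n);
        for (int k2 = 0; k2 < K; ++k2) { pp[k2] = std::exp(pp[k2] - mx); sum += pp[k2]; }
        for (int k2 = 0; k2 < K; ++k2) pp[k2] = (float)(pp[k2] / sum);
        loss -= std::log(std::max((double)pp[y[idx[n] - 1]], 1e-12)) / N;
      }
      if (!std::isfinite(loss))
        stop("training diverged (non-finite loss) at epoch %d", e + 1);
      ep_loss += loss * N;

      arma::fmat dlogits = probs;
      for (int n = 0; n < N; ++n) dlogits(y[idx[n] - 1], n) -= 1.0f;
      dlogits /= (float)N;

      arma::fmat dWd, dZ;
      gemm_f(dWd, Z, false, dlogits, true);
      arma::fvec dbd = arma::sum(dlogits, 1);
      gemm_f(dZ, Wdf, false, dlogits, false);

      arma::fmat dtop(P * (size_t)N, C);
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < C; ++c)
          std::copy(dZ.colptr(n) + (size_t)c * P,
                    dZ.colptr(n) + (size_t)c * P + P,
                    dtop.colptr(c) + (size_t)n * P);

      std::vector<arma::fmat> dW;
      std::vector<arma::fvec> db, dgamma, dbeta;
      std::vector<bool> have;
      arma::fmat dcolT;
      encoder_bwd(blocks, cache, N, stride, pad, (float)slope, frozen,
                  n_layers, dtop, dW, db, dgamma, dbeta, have, dcolT);

      ++t;
      for (int i = 0; i < n_layers; ++i) {
        if (!have[i]) continue;
        adam_apply(masters[i].W, dW[i].memptr(), stW[i], lr, t);
        adam_apply(masters[i].b, db[i].memptr(), stB[i], lr, t);
        adam_apply(masters[i].gamma, dgamma[i].memptr(), stG[i], lr, t);
        adam_apply(masters[i].beta, dbeta[i].memptr(), stBt[i], lr, t);
        fold_bn_back(masters[i], blocks[i]);
      }
      adam_apply(Wd, dWd.memptr(), stWd, lr, t);
      adam_apply(bd, dbd.memptr(), stBd, lr, t);
    }
    history[e] = ep_loss / n_total;
  }
  NumericVector Wd_out = dvec_to_r(Wd);
  Wd_out.attr("dim") = IntegerVector::create(latent, K);
  return List::create(
    _["encoder"] = masters_to_r(masters, false),
    _["dense"] = List::create(_["W"] = Wd_out, _["b"] = dvec_to_r(bd)),
    _["history"] = history);
}

// [[Rcpp::export]]
List cpp_cae_train(NumericVector x, List enc, List dec, double slope,
                   int stride, int pad, int out_act, double lr,
                   int batch_size, List orders)
{
  IntegerVector dm = x.attr("dim");
  const int n_total = dm[4];
  std::vector<MasterBlock> emast = load_masters(enc);
  std::vector<MasterBlock> dmast = load_masters(dec);
  const int n_layers = emast.size();

  std::vector<AdamBuf> esW(n_layers), esB(n_layers), esG(n_layers), esBt(n_layers);
  std::vector<AdamBuf> dsW(n_layers), dsB(n_layers), dsG(n_layers), dsBt(n_layers);
  long t = 0;
  const int n_epochs = orders.size();
  NumericVector history(n_epochs);

  std::vector<LayerCache> ecache(1), dcache;
  arma::fmat x_keep, dtop, dcolT, colT_ws;
  for (int e = 0; e < n_epochs; ++e) {
    IntegerVector ord = orders[e];
    double ep_loss = 0.0;
    for (int start = 0; start < ord.size(); start += batch_size) {
      const int len = std::min((int)ord.size() - start, batch_size);
      IntegerVector idx(len);
      for (int q = 0; q < len; ++q) idx[q] = ord[start + q];

      std::vector<BlockP> eblocks, dblocks;
      for (int i = 0; i < n_layers; ++i) {
        eblocks.push_back(master_view(emast[i], false));
        dblocks.push_back(master_view(dmast[i], true));
      }
      int D, H, W, N;
      load_input(x, idx, ecache[0].act, D, H, W, N);
      x_keep = ecache[0].act;
      encoder_fwd(eblocks, ecache, Shape3{D, H, W}, N, stride, pad,
                  (float)slope, true, 0, n_layers, true);
      decoder_fwd(dblocks, dcache, ecache[n_layers].act,
                  ecache[n_layers].out_shape, N, stride, pad, (float)slope,
                  true, out_act, true);

      arma::fmat& out = dcache[n_layers].act;
      const double numel = (double)out.n_elem;
      double loss = 0;
      dtop.set_size(out.n_rows, out.n_cols);
      {
        const float* op = out.memptr();
        const float* xp = x_keep.memptr();
        float* dp = dtop.memptr();
        for (size_t q = 0; q < out.n_elem; ++q) {
          const double diff = (double)op[q] - xp[q];
          loss += diff * diff;
          dp[q] = (float)(2.0 * diff / numel);
        }
        loss /= numel;
      }
      if (!std::isfinite(loss))
        stop("training diverged (non-finite loss) at epoch %d", e + 1);
      ep_loss += loss * N;

      std::vector<arma::fmat> ddW, edW;
      std::vector<arma::fvec> ddb, ddg, ddbt, edb, edg, edbt;
      std::vector<bool> ehave;
      decoder_bwd(dblocks, dcache, N, stride, pad, (float)slope, out_act,
                  dtop, ddW, ddb, ddg, ddbt, colT_ws);
      encoder_bwd(eblocks, ecache, N, stride, pad, (float)slope, 0,
                  n_layers, dtop, edW, edb, edg, edbt, ehave, dcolT);

      ++t;
      for (int i = 0; i < n_layers; ++i) {
        adam_apply(emast[i].W, edW[i].memptr(), esW[i], lr, t);
        adam_apply(emast[i].b, edb[i].memptr(), esB[i], lr, t);
        adam_apply(emast[i].gamma, edg[i].memptr(), esG[i], lr, t);
        adam_apply(emast[i].beta, edbt[i].memptr(), esBt[i], lr, t);
        fold_bn_back(emast[i], eblocks[i]);
        adam_apply(dmast[i].W, ddW[i].memptr(), dsW[i], lr, t);
        adam_apply(dmast[i].b, ddb[i].memptr(), dsB[i], lr, t);
        if (dmast[i].has_bn) {
          adam_apply(dmast[i].gamma, ddg[i].memptr(), dsG[i], lr, t);
          adam_apply(dmast[i].beta, ddbt[i].memptr(), dsBt[i], lr, t);
          fold_bn_back(dmast[i], dblocks[i]);
        }
      }
    }
    history[e] = ep_loss / n_total;
  }
  return List::create(
    _["encoder"] = masters_to_r(emast, false),
    _["decoder"] = masters_to_r(dmast, true),
    _["history"] = history);
}

// [[Rcpp::export]]
List cpp_cnn_train_step(NumericVector x, IntegerVector idx, IntegerVector y,
                        List enc, List dense,
                        int frozen, double slope, int stride, int pad)
{
  static std::vector<LayerCache> cache;
  static arma::fmat Z, dZ, dtop, dcolT, dWd;
  int D, H, W, N;
  if (cache.empty()) cache.resize(1);
  load_input(x, idx, cache[0].act, D, H, W, N);
  std::vector<BlockP> blocks = load_blocks(enc, false);
  const int n_layers = blocks.size();
  encoder_fwd(blocks, cache, Shape3{D, H, W}, N, stride, pad,
              (float)slope, true, frozen, n_layers, true);

  // flatten latent: sample n's vector is (position, channel) column-major
  LayerCache& top = cache[n_layers];
  const size_t P = top.out_shape.prod();
  const int C = top.act.n_cols;
  const size_t latent = P * C;
  Z.set_size(latent, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      std::copy(top.act.colptr(c) + (size_t)n * P,
                top.act.colptr(c) + (size_t)n * P + P,
                Z.colptr(n) + (size_t)c * P);

  NumericMatrix Wd_r = dense["W"];
  NumericVector bd_r = dense["b"];
  const int K = Wd_r.ncol();
  arma::fmat Wd(latent, K);
  std::copy(Wd_r.begin(), Wd_r.end(), Wd.memptr());
  arma::fvec bd = arma::conv_to<arma::fvec>::from(as<arma::vec>(bd_r));

  arma::fmat logits;
  gemm_f(logits, Wd, true, Z, false);
  logits.each_col() += bd;
  double loss = 0;
  arma::fmat probs = logits;
  for (int n = 0; n < N; ++n) {
    float mx = probs.col(n).max();
    double sum = 0;
    float* pp = probs.colptr(n);
    for (int k2 = 0; k2 < K; ++k2) { pp[k2] = std::exp(pp[k2] - mx); sum += pp[k2]; }
    for (int k2 = 0; k2 < K; ++k2) pp[k2] = (float)(pp[k2] / sum);
    loss -= std::log(std::max((double)pp[y[n]], 1e-12)) / N;
  }
  arma::fmat dlogits = probs;
  for (int n = 0; n < N; ++n) dlogits(y[n], n) -= 1.0f;
  dlogits /= (float)N;

  gemm_f(dWd, Z, false, dlogits, true);
  arma::fvec dbd = arma::sum(dlogits, 1);
  gemm_f(dZ, Wd, false, dlogits, false);

  dtop.set_size(P * (size_t)N, C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      std::copy(dZ.colptr(n) + (size_t)c * P,
                dZ.colptr(n) + (size_t)c * P + P,
                dtop.colptr(c) + (size_t)n * P);

  std::vector<arma::fmat> dW;
  std::vector<arma::fvec> db, dgamma, dbeta;
  std::vector<bool> have;
  encoder_bwd(blocks, cache, N, stride, pad, (float)slope, frozen, n_layers,
              dtop, dW, db, dgamma, dbeta, have, dcolT);

  NumericVector dWd_r(dWd.n_elem);
  std::copy(dWd.memptr(), dWd.memptr() + dWd.n_elem, REAL(dWd_r));
  dWd_r.attr("dim") = IntegerVector::create((int)latent, K);

  return List::create(
    _["loss"] = loss,
    _["encoder"] = pack_enc_grads(dW, db, dgamma, dbeta, have, blocks),
    _["dense"] = List::create(_["W"] = dWd_r, _["b"] = fvec_to_r(dbd)),
    _["running"] = pack_running(blocks, frozen));
}

// [[Rcpp::export]]
NumericVector cpp_encoder_infer(NumericVector x, List enc, int upto,
                                double slope, int stride, int pad)
{
  static std::vector<LayerCache> cache;
  if (cache.empty()) cache.resize(1);
  int D, H, W, N;
  load_input(x, IntegerVector(0), cache[0].act, D, H, W, N);
  std::vector<BlockP> blocks = load_blocks(enc, false);
  encoder_fwd(blocks, cache, Shape3{D, H, W}, N, stride, pad,
              (float)slope, false, 0, upto, false);
  LayerCache& top = cache[upto];
  const size_t P = top.out_shape.prod();
  const int C = top.act.n_cols;
  NumericVector out(P * (size_t)C * N);
  double* op = REAL(out);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float* src = top.act.colptr(c) + (size_t)n * P;
      double* dst = op + ((size_t)n * C + c) * P;
      for (size_t q = 0; q < P; ++q) dst[q] = src[q];
    }
  out.attr("dim") = IntegerVector::create(top.out_shape.d, top.out_shape.h,
                                          top.out_shape.w, C, N);
  return out;
}

// [[Rcpp::export]]
List cpp_cae_train_step(NumericVector x, IntegerVector idx, List enc,
                        List dec, double slope,
                        int stride, int pad, int out_act)
{
  static std::vector<LayerCache> ecache, dcache;
  static arma::fmat x_keep, dtop, dcolT, colT_ws;
  int D, H, W, N;
  if (ecache.empty()) ecache.resize(1);
  load_input(x, idx, ecache[0].act, D, H, W, N);
  x_keep = ecache[0].act;  // reconstruction target
  std::vector<BlockP> eblocks = load_blocks(enc, false);
  std::vector<BlockP> dblocks = load_blocks(dec, true);
  const int n_layers = eblocks.size();
  encoder_fwd(eblocks, ecache, Shape3{D, H, W}, N, stride, pad,
              (float)slope, true, 0, n_layers, true);
  decoder_fwd(dblocks, dcache, ecache[n_layers].act,
              ecache[n_layers].out_shape, N, stride, pad, (float)slope,
              true, out_act, true);

  arma::fmat& out = dcache[n_layers].act;
  const double numel = (double)out.n_elem;
  double loss = 0;
  dtop.set_size(out.n_rows, out.n_cols);
  {
    const float* op = out.memptr();
    const float* xp = x_keep.memptr();
    float* dp = dtop.memptr();
    for (size_t q = 0; q < out.n_elem; ++q) {
      const double diff = (double)op[q] - xp[q];
      loss += diff * diff;
      dp[q] = (float)(2.0 * diff / numel);
    }
    loss /= numel;
  }

  std::vector<arma::fmat> ddW, edW;
  std::vector<arma::fvec> ddb, ddg, ddbt, edb, edg, edbt;
  std::vector<bool> ehave;
  decoder_bwd(dblocks, dcache, N, stride, pad, (float)slope, out_act,
              dtop, ddW, ddb, ddg, ddbt, colT_ws);
  encoder_bwd(eblocks, ecache, N, stride, pad, (float)slope, 0, n_layers,
              dtop, edW, edb, edg, edbt, ehave, dcolT);

  List dgrads(dblocks.size());
  for (size_t i = 0; i < dblocks.size(); ++i) {
    if (dblocks[i].has_bn) {
      dgrads[i] = List::create(_["W"] = fmat_to_r(ddW[i], dblocks[i].wdim),
                               _["b"] = fvec_to_r(ddb[i]),
                               _["gamma"] = fvec_to_r(ddg[i]),
                               _["beta"] = fvec_to_r(ddbt[i]));
    } else {
      dgrads[i] = List::create(_["W"] = fmat_to_r(ddW[i], dblocks[i].wdim),
                               _["b"] = fvec_to_r(ddb[i]));
    }
  }
  return List::create(
    _["loss"] = loss,
    _["encoder"] = pack_enc_grads(edW, edb, edg, edbt, ehave, eblocks),
    _["decoder"] = dgrads,
    _["enc_running"] = pack_running(eblocks, 0),
    _["dec_running"] = pack_running(dblocks, 0));
}

// [[Rcpp::export]]
NumericVector cpp_cae_infer(NumericVector x, List enc, List dec, double slope,
                            int stride, int pad, int out_act)
{
  static std::vector<LayerCache> ecache, dcache;
  if (ecache.empty()) ecache.resize(1);
  int D, H, W, N;
  load_input(x, IntegerVector(0), ecache[0].act, D, H, W, N);
  std::vector<BlockP> eblocks = load_blocks(enc, false);
  std::vector<BlockP> dblocks = load_blocks(dec, true);
  const int n_layers = eblocks.size();
  encoder_fwd(eblocks, ecache, Shape3{D, H, W}, N, stride, pad,
              (float)slope, false, 0, n_layers, false);
  decoder_fwd(dblocks, dcache, ecache[n_layers].act,
              ecache[n_layers].out_shape, N, stride, pad, (float)slope,
              false, out_act, false);
  arma::fmat& out = dcache[n_layers].act;
  const size_t P = (size_t)dcache[n_layers].out_shape.prod();
  NumericVector r(out.n_elem);
  double* rp = REAL(r);
  for (int n = 0; n < N; ++n) {
    const float* src = out.memptr() + (size_t)n * P;
    double* dst = rp + (size_t)n * P;
    for (size_t q = 0; q < P; ++q) dst[q] = src[q];
  }
  r.attr("dim") = IntegerVector::create(dcache[n_layers].out_shape.d,
                                        dcache[n_layers].out_shape.h,
                                        dcache[n_layers].out_shape.w, 1, N);
  return r;
}
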