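// Fused element-wise kernels for the transformer forward/backward passes.
// All matrices are column-major (R layout); batched token sequences use the
// batch-fastest row convention documented in model-core.R. These kernels
// exist to avoid repeated full-matrix temporaries in R; all heavy matrix
// products stay in BLAS.

#include <Rcpp.h>
using namespace Rcpp;

static inline NumericMatrix alloc_mat(int nr, int nc) {
  return NumericMatrix(Rcpp::no_init(nr, nc));
}

// out[i,j] = M[i,j] + b[j]
// [[Rcpp::export]]
NumericMatrix add_bias_cpp(const NumericMatrix& M, const NumericVector& b) {
  int nr = M.nrow(), nc = M.ncol();
  NumericMatrix out = alloc_mat(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double bj = b[j];
    const double* src = &M(0, j);
    double* dst = &out(0, j);
    for (int i = 0; i < nr; ++i) dst[i] = src[i] + bj;
  }
  return out;
}

// token-wise (row) normalisation: out = xhat * g + b with per-row statistics
// [[Rcpp::export]]
List ln_fwd_cpp(const NumericMatrix& X, const NumericVector& g,
                const NumericVector& b, double eps) {
  int nr = X.nrow(), nc = X.ncol();
  NumericMatrix out = alloc_mat(nr, nc), xhat = alloc_mat(nr, nc);
  NumericVector inv(nr);
  std::vector<double> mu(nr, 0.0), sq(nr, 0.0);
  for (int j = 0; j < nc; ++j) {
    const double* src = &X(0, j);
    for (int i = 0; i < nr; ++i) { mu[i] += src[i]; sq[i] += src[i] * src[i]; }
  }
  for (int i = 0; i < nr; ++i) {
    mu[i] /= nc;
    double var = sq[i] / nc - mu[i] * mu[i];
    inv[i] = 1.0 / std::sqrt((var > 0 ? var : 0) + eps);
  }
  for (int j = 0; j < nc; ++j) {
    const double gj = g[j], bj = b[j];
    const double* src = &X(0, j);
    double* xh = &xhat(0, j);
    double* o = &out(0, j);
    for (int i = 0; i < nr; ++i) {
      xh[i] = (src[i] - mu[i]) * inv[i];
      o[i] = xh[i] * gj + bj;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List ln_bwd_cpp(const NumericMatrix& dout, const NumericMatrix& xhat,
                const NumericVector& inv, const NumericVector& g) {
  int nr = dout.nrow(), nc = dout.ncol();
  NumericMatrix dX = alloc_mat(nr, nc);
  NumericVector dg(nc), db(nc);
  std::vector<double> m1(nr, 0.0), m2(nr, 0.0);
  for (int j = 0; j < nc; ++j) {
    const double gj = g[j];
    const double* d = &dout(0, j);
    const double* xh = &xhat(0, j);
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < nr; ++i) {
      double dxh = d[i] * gj;
      m1[i] += dxh;
      m2[i] += dxh * xh[i];
      sg += d[i] * xh[i];
      sb += d[i];
    }
    dg[j] = sg; db[j] = sb;
  }
  for (int i = 0; i < nr; ++i) { m1[i] /= nc; m2[i] /= nc; }
  for (int j = 0; j < nc; ++j) {
    const double gj = g[j];
    const double* d = &dout(0, j);
    const double* xh = &xhat(0, j);
    double* dx = &dX(0, j);
    for (int i = 0; i < nr; ++i)
      dx[i] = inv[i] * (d[i] * gj - m1[i] - xh[i] * m2[i]);
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dg, _["dbeta"] = db);
}

// feature-wise (column) batch normalisation, training mode (batch stats)
// [[Rcpp::export]]
List bn_fwd_train_cpp(const NumericMatrix& X, const NumericVector& g,
                      const NumericVector& b, double eps) {
  int nr = X.nrow(), nc = X.ncol();
  NumericMatrix out = alloc_mat(nr, nc), xhat = alloc_mat(nr, nc);
  NumericVector mu(nc), var(nc), inv(nc);
  for (int j = 0; j < nc; ++j) {
    const double* src = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < nr; ++i) s += src[i];
    double m = s / nr;
    double v = 0.0;
    for (int i = 0; i < nr; ++i) { double c = src[i] - m; v += c * c; }
    v /= nr;
    double iv = 1.0 / std::sqrt(v + eps);
    mu[j] = m; var[j] = v; inv[j] = iv;
    const double gj = g[j], bj = b[j];
    double* xh = &xhat(0, j);
    double* o = &out(0, j);
    for (int i = 0; i < nr; ++i) {
      xh[i] = (src[i] - m) * iv;
      o[i] = xh[i] * gj + bj;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv,
                      _["mu"] = mu, _["var"] = var);
}

// eval mode: normalise with running statistics
// [[Rcpp::export]]
List bn_fwd_eval_cpp(const NumericMatrix& X, const NumericVector& g,
                     const NumericVector& b, const NumericVector& rmean,
                     const NumericVector& rvar, double eps) {
  int nr = X.nrow(), nc = X.ncol();
  NumericMatrix out = alloc_mat(nr, nc), xhat = alloc_mat(nr, nc);
  NumericVector inv(nc);
  for (int j = 0; j < nc; ++j) {
    double iv = 1.0 / std::sqrt(rvar[j] + eps);
    inv[j] = iv;
    const double m = rmean[j], gj = g[j], bj = b[j];
    const double* src = &X(0, j);
    double* xh = &xhat(0, j);
    double* o = &out(0, j);
    for (int i = 0; i < nr; ++i) {
      xh[i] = (src[i] - m) * iv;
      o[i] = xh[i] * gj + bj;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List bn_bwd_cpp(const NumericMatrix& dout, const NumericMatrix& xhat,
                const NumericVector& inv, const NumericVector& g) {
  int nr = dout.nrow(), nc = dout.ncol();
  NumericMatrix dX = alloc_mat(nr, nc);
  NumericVector dg(nc), db(nc);
  for (int j = 0; j < nc; ++j) {
    const double gj = g[j];
    const double* d = &dout(0, j);
    const double* xh = &xhat(0, j);
    double m1 = 0.0, m2 = 0.0, sg = 0.0, sb = 0.0;
    for (int i = 0; i < nr; ++i) {
      double dxh = d[i] * gj;
      m1 += dxh;
      m2 += dxh * xh[i];
      sg += d[i] * xh[i];
      sb += d[i];
    }
    dg[j] = sg; db[j] = sb;
    m1 /= nr; m2 /= nr;
    double* dx = &dX(0, j);
    for (int i = 0; i < nr; ++i)
      dx[i] = inv[j] * (d[i] * gj - m1 - xh[i] * m2);
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dg, _["dbeta"] = db);
}

// [[Rcpp::export]]
NumericMatrix relu_cpp(const NumericMatrix& M) {
  int nr = M.nrow(), nc = M.ncol();
  NumericMatrix out = alloc_mat(nr, nc);
  const double* src = M.begin();
  double* dst = out.begin();
  R_xlen_t n = (R_xlen_t)nr * nc;
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = src[i] > 0 ? src[i] : 0.0;
  return out;
}

// dout masked by the sign of the forward activation input/output
// [[Rcpp::export]]
NumericMatrix drelu_cpp(const NumericMatrix& dout, const NumericMatrix& act) {
  int nr = dout.nrow(), nc = dout.ncol();
  NumericMatrix out = alloc_mat(nr, nc);
  const double* d = dout.begin();
  const double* a = act.begin();
  double* dst = out.begin();
  R_xlen_t n = (R_xlen_t)nr * nc;
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = a[i] > 0 ? d[i] : 0.0;
  return out;
}

// rotate consecutive column pairs (2p-1, 2p) by angles with cos C, sin S;
// C and S have ncol(M)/2 columns. invert = true applies the inverse rotation.
// [[Rcpp::export]]
NumericMatrix rope_rot_cpp(const NumericMatrix& M, const NumericMatrix& C,
                           const NumericMatrix& S, bool invert) {
  int nr = M.nrow(), np = M.ncol() / 2;
  NumericMatrix out = alloc_mat(nr, 2 * np);
  const double sgn = invert ? -1.0 : 1.0;
  for (int p = 0; p < np; ++p) {
    const double* a = &M(0, 2 * p);
    const double* b = &M(0, 2 * p + 1);
    const double* cc = &C(0, p);
    const double* ss = &S(0, p);
    double* oa = &out(0, 2 * p);
    double* ob = &out(0, 2 * p + 1);
    for (int i = 0; i < nr; ++i) {
      double s = sgn * ss[i];
      oa[i] = a[i] * cc[i] - b[i] * s;
      ob[i] = a[i] * s + b[i] * cc[i];
    }
  }
  return out;
}

// gradient of the rotation angle: dphi[i,p] = dR_odd*(-R_even) + dR_even*R_odd
// [[Rcpp::export]]
NumericMatrix rope_phase_grad_cpp(const NumericMatrix& dRot,
                                  const NumericMatrix& Rot) {
  int nr = dRot.nrow(), np = dRot.ncol() / 2;
  NumericMatrix out = alloc_mat(nr, np);
  for (int p = 0; p < np; ++p) {
    const double* da = &dRot(0, 2 * p);
    const double* db = &dRot(0, 2 * p + 1);
    const double* a = &Rot(0, 2 * p);
    const double* b = &Rot(0, 2 * p + 1);
    double* o = &out(0, p);
    for (int i = 0; i < nr; ++i) o[i] = -da[i] * b[i] + db[i] * a[i];
  }
  return out;
}

// center-query attention scores: s[r,h] = sum_j K[r, hj] * Q[b(r), hj]
// where b(r) = (r mod Nb) indexes the batch item of row r.
// [[Rcpp::export]]
NumericMatrix head_scores_cpp(const NumericMatrix& K, const NumericMatrix& Q,
                              int Nb, int k) {
  int nr = K.nrow(), d = K.ncol(), dh = d / k;
  NumericMatrix out(nr, k);
  for (int h = 0; h < k; ++h) {
    double* o = &out(0, h);
    for (int jj = 0; jj < dh; ++jj) {
      int j = h * dh + jj;
      const double* kc = &K(0, j);
      const double* qc = &Q(0, j);
      for (int r = 0; r < nr; ++r) o[r] += kc[r] * qc[r % Nb];
    }
  }
  return out;
}

// backward of head_scores: dK[r,hj] = ds[r,h] * Q[b(r),hj];
// dQ[b,hj] = sum_{r: b(r)=b} ds[r,h] * K[r,hj]
// [[Rcpp::export]]
List head_scores_bwd_cpp(const NumericMatrix& ds, const NumericMatrix& K,
                         const NumericMatrix& Q, int Nb) {
  int nr = K.nrow(), d = K.ncol(), k = ds.ncol(), dh = d / k;
  NumericMatrix dK = alloc_mat(nr, d), dQ(Nb, d);
  for (int h = 0; h < k; ++h) {
    const double* dsc = &ds(0, h);
    for (int jj = 0; jj < dh; ++jj) {
      int j = h * dh + jj;
      const double* kc = &K(0, j);
      const double* qc = &Q(0, j);
      double* dkc = &dK(0, j);
      double* dqc = &dQ(0, j);
      for (int r = 0; r < nr; ++r) {
        dkc[r] = dsc[r] * qc[r % Nb];
        dqc[r % Nb] += dsc[r] * kc[r];
      }
    }
  }
  return List::create(_["dK"] = dK, _["dQ"] = dQ);
}

// attention-value mixing: o[b, hj] = sum_r A[r,h] * V[r,hj] over rows of
// batch item b
// [[Rcpp::export]]
NumericMatrix value_mix_cpp(const NumericMatrix& A, const NumericMatrix& V,
                            int Nb) {
  int nr = V.nrow(), d = V.ncol(), k = A.ncol(), dh = d / k;
  NumericMatrix out(Nb, d);
  for (int h = 0; h < k; ++h) {
    const double* ac = &A(0, h);
    for (int jj = 0; jj < dh; ++jj) {
      int j = h * dh + jj;
      const double* vc = &V(0, j);
      double* o = &out(0, j);
      for (int r = 0; r < nr; ++r) o[r % Nb] += ac[r] * vc[r];
    }
  }
  return out;
}

// backward of value_mix: dV[r,hj] = A[r,h]*do[b(r),hj];
// dA[r,h] = sum_j V[r,hj]*do[b(r),hj]
// [[Rcpp::export]]
List value_mix_bwd_cpp(const NumericMatrix& A, const NumericMatrix& V,
                       const NumericMatrix& dout, int Nb) {
  int nr = V.nrow(), d = V.ncol(), k = A.ncol(), dh = d / k;
  NumericMatrix dV = alloc_mat(nr, d), dA(nr, k);
  for (int h = 0; h < k; ++h) {
    const double* ac = &A(0, h);
    double* dac = &dA(0, h);
    for (int jj = 0; jj < dh; ++jj) {
      int j = h * dh + jj;
      const double* vc = &V(0, j);
      const double* doc = &dout(0, j);
      double* dvc = &dV(0, j);
      for (int r = 0; r < nr; ++r) {
        double dd = doc[r % Nb];
        dvc[r] = ac[r] * dd;
        dac[r] += vc[r] * dd;
      }
    }
  }
  return List::create(_["dV"] = dV, _["dA"] = dA);
}

// row-wise softmax over groups of a (Nb*n) x k score matrix, softmaxing
// over the token dimension t for fixed (batch item, head):
// rows r = b + t*Nb. Returns same-shape normalised weights.
// [[Rcpp::export]]
NumericMatrix token_softmax_cpp(const NumericMatrix& S, int Nb) {
  int nr = S.nrow(), k = S.ncol(), n = nr / Nb;
  NumericMatrix out(nr, k);
  for (int h = 0; h < k; ++h) {
    const double* s = &S(0, h);
    double* o = &out(0, h);
    for (int b = 0; b < Nb; ++b) {
      double mx = -INFINITY;
      for (int t = 0; t < n; ++t) mx = std::max(mx, s[b + (R_xlen_t)t * Nb]);
      double z = 0.0;
      for (int t = 0; t < n; ++t) {
        R_xlen_t r = b + (R_xlen_t)t * Nb;
        double e = std::exp(s[r] - mx);
        o[r] = e;
        z += e;
      }
      for (int t = 0; t < n; ++t) o[b + (R_xlen_t)t * Nb] /= z;
    }
  }
  return out;
}

// backward of token_softmax: dS = A * (dA - sum_t A*dA) per (item, head)
// [[Rcpp::export]]
NumericMatrix token_softmax_bwd_cpp(const NumericMatrix& dA,
                                    const NumericMatrix& A, int Nb) {
  int nr = A.nrow(), k = A.ncol(), n = nr / Nb;
  NumericMatrix out(nr, k);
  for (int h = 0; h < k; ++h) {
    const double* da = &dA(0, h);
    const double* a = &A(0, h);
    double* o = &out(0, h);
    for (int b = 0; b < Nb; ++b) {
      double dot = 0.0;
      for (int t = 0; t < n; ++t) {
        R_xlen_t r = b + (R_xlen_t)t * Nb;
        dot += a[r] * da[r];
      }
      for (int t = 0; t < n; ++t) {
        R_xlen_t r = b + (R_xlen_t)t * Nb;
        o[r] = a[r] * (da[r] - dot);
      }
    }
  }
  return out;
}
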