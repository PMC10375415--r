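// Fused dense output layer kept in single precision (the customary
// deep-learning weight precision). The output layer holds ~90% of the
// model's parameters, and batch-4 training is bound by parameter-array
// memory traffic, so keeping weights, moments and gradients as floats
// with fused passes roughly halves the per-batch cost. The trained
// weights are exported back to R doubles for prediction and
// serialization.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct OutLayer {
  int din, dout;
  std::vector<float> W, b, mW, vW, mb, vb, G, gb;
};

// [[Rcpp::export]]
SEXP cpp_out_create(NumericMatrix W0, NumericVector b0) {
  OutLayer* L = new OutLayer();
  L->din = W0.nrow();
  L->dout = W0.ncol();
  size_t n = (size_t)L->din * L->dout;
  L->W.resize(n); L->mW.assign(n, 0.f); L->vW.assign(n, 0.f);
  L->G.assign(n, 0.f);
  L->b.resize(L->dout); L->mb.assign(L->dout, 0.f);
  L->vb.assign(L->dout, 0.f); L->gb.assign(L->dout, 0.f);
  // internal storage is row-major (outputs contiguous per input)
  for (int k = 0; k < L->din; ++k)
    for (int j = 0; j < L->dout; ++j)
      L->W[(size_t)k * L->dout + j] = (float)W0(k, j);
  for (int j = 0; j < L->dout; ++j) L->b[j] = (float)b0[j];
  XPtr<OutLayer> p(L, true);
  return p;
}

// [[Rcpp::export]]
NumericMatrix cpp_out_forward(SEXP ptr, NumericMatrix A, bool tanh_act) {
  XPtr<OutLayer> L(ptr);
  int n = A.nrow(), din = A.ncol(), dout = L->dout;
  if (din != L->din) stop("input width mismatch");
  NumericMatrix Z(n, dout);
  std::vector<float> acc((size_t)dout);
  for (int s = 0; s < n; ++s) {
    for (int j = 0; j < dout; ++j) acc[j] = L->b[j];
    for (int k = 0; k < din; ++k) {
      float a = (float)A(s, k);
      const float* w = &L->W[(size_t)k * dout];
      for (int j = 0; j < dout; ++j) acc[j] += a * w[j];
    }
    if (tanh_act)
      for (int j = 0; j < dout; ++j) Z(s, j) = std::tanh((double)acc[j]);
    else
      for (int j = 0; j < dout; ++j) Z(s, j) = (double)acc[j];
  }
  return Z;
}

// Err is dLoss/d(activation); Aout the tanh output from the forward
// pass. Stores the weight gradient internally and returns the
// gradient w.r.t. the layer input.
// [[Rcpp::export]]
NumericMatrix cpp_out_backward(SEXP ptr, NumericMatrix A,
                               NumericMatrix Aout, NumericMatrix Err,
                               bool tanh_act) {
  XPtr<OutLayer> L(ptr);
  int n = A.nrow(), din = L->din, dout = L->dout;
  std::vector<float> delta((size_t)n * dout);
  for (int s = 0; s < n; ++s)
    for (int j = 0; j < dout; ++j) {
      double d = Err(s, j);
      if (tanh_act) {
        double a = Aout(s, j);
        d *= (1.0 - a * a);
      }
      delta[(size_t)s * dout + j] = (float)d;
    }
  std::fill(L->G.begin(), L->G.end(), 0.f);
  std::fill(L->gb.begin(), L->gb.end(), 0.f);
  NumericMatrix Din(n, din);
  for (int s = 0; s < n; ++s) {
    const float* dl = &delta[(size_t)s * dout];
    for (int j = 0; j < dout; ++j) L->gb[j] += dl[j];
    for (int k = 0; k < din; ++k) {
      float a = (float)A(s, k);
      float* g = &L->G[(size_t)k * dout];
      const float* w = &L->W[(size_t)k * dout];
      float acc = 0.f;
      for (int j = 0; j < dout; ++j) {
        g[j] += a * dl[j];
        acc += w[j] * dl[j];
      }
      Din(s, k) = (double)acc;
    }
  }
  return Din;
}

// [[Rcpp::export]]
void cpp_out_adam(SEXP ptr, double lr, double t, double b1, double b2,
                  double eps) {
  XPtr<OutLayer> L(ptr);
  float c1 = (float)(1.0 - std::pow(b1, t));
  float c2 = (float)(1.0 - std::pow(b2, t));
  float fb1 = (float)b1, fb2 = (float)b2, flr = (float)lr,
    fe = (float)eps;
  size_t n = L->W.size();
  float* w = L->W.data();
  float* g = L->G.data();
  float* m = L->mW.data();
  float* v = L->vW.data();
  for (size_t i = 0; i < n; ++i) {
    m[i] = fb1 * m[i] + (1.f - fb1) * g[i];
    v[i] = fb2 * v[i] + (1.f - fb2) * g[i] * g[i];
    w[i] -= flr * (m[i] / c1) / (std::sqrt(v[i] / c2) + fe);
  }
  for (int j = 0; j < L->dout; ++j) {
    L->mb[j] = fb1 * L->mb[j] + (1.f - fb1) * L->gb[j];
    L->vb[j] = fb2 * L->vb[j] + (1.f - fb2) * L->gb[j] * L->gb[j];
    L->b[j] -= flr * (L->mb[j] / c1) /
      (std::sqrt(L->vb[j] / c2) + fe);
  }
}

// [[Rcpp::export]]
List cpp_out_export(SEXP ptr) {
  XPtr<OutLayer> L(ptr);
  NumericMatrix W(L->din, L->dout);
  NumericVector b(L->dout);
  for (int k = 0; k < L->din; ++k)
    for (int j = 0; j < L->dout; ++j)
      W(k, j) = (double)L->W[(size_t)k * L->dout + j];
  for (int j = 0; j < L->dout; ++j) b[j] = (double)L->b[j];
  return List::create(_["W"] = W, _["b"] = b);
}

// [[Rcpp::export]]
void cpp_out_import(SEXP ptr, NumericMatrix W, NumericVector b) {
  XPtr<OutLayer> L(ptr);
  if (W.nrow() != L->din || W.ncol() != L->dout)
    stop("shape mismatch");
  for (int k = 0; k < L->din; ++k)
    for (int j = 0; j < L->dout; ++j)
      L->W[(size_t)k * L->dout + j] = (float)W(k, j);
  for (int j = 0; j < L->dout; ++j) L->b[j] = (float)b[j];
}
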