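// In-place Adam parameter update: one fused pass over the parameter
// block, no intermediate allocations (the R caller owns copy semantics
// and deep-copies checkpoints explicitly).

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
void cpp_adam_update(NumericVector W, NumericVector G, NumericVector M,
                     NumericVector V, double lr, double t, double b1,
                     double b2, double eps) {
  R_xlen_t n = W.size();
  if (G.size() != n || M.size() != n || V.size() != n)
    stop("parameter/gradient/state length mismatch");
  double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  double* w = REAL(W);
  double* g = REAL(G);
  double* m = REAL(M);
  double* v = REAL(V);
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * g[i];
    v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    w[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_lrelu(NumericMatrix Z, double alpha) {
  NumericMatrix A(Z.nrow(), Z.ncol());
  R_xlen_t n = Z.size();
  const double* z = REAL(Z);
  double* a = REAL(A);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = z[i] > 0 ? z[i] : alpha * z[i];
  return A;
}

// derivative of leaky ReLU given pre-activation, times upstream delta
// (in place on delta)
// [[Rcpp::export]]
void cpp_lrelu_bwd(NumericMatrix Delta, NumericMatrix Z, double alpha) {
  R_xlen_t n = Delta.size();
  if (Z.size() != n) stop("shape mismatch");
  double* d = REAL(Delta);
  const double* z = REAL(Z);
  for (R_xlen_t i = 0; i < n; ++i) if (z[i] <= 0) d[i] *= alpha;
}
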