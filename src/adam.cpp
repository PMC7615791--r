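#pragma GCC optimize("O3,no-math-errno,tree-vectorize")
#pragma GCC target("avx2,fma")
#include <Rcpp.h>
using namespace Rcpp;

// One fused Adam update for a single parameter tensor. The first and second
// moment buffers are updated in place (they are owned by the optimizer
// state and never shared); the updated parameters are returned as a fresh
// vector so checkpoint references to the old parameters stay valid.
// [[Rcpp::export]]
NumericVector adam_kernel(NumericVector p, NumericVector g,
                          NumericVector m, NumericVector v,
                          double lr, double beta1, double beta2,
                          double c1, double c2, double eps) {
  R_xlen_t n = p.size();
  NumericVector out = no_init(n);
  double *pp = REAL(p), *pg = REAL(g), *pm = REAL(m), *pv = REAL(v),
         *po = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i];
    double mi = beta1 * pm[i] + (1.0 - beta1) * gi;
    double vi = beta2 * pv[i] + (1.0 - beta2) * gi * gi;
    pm[i] = mi;
    pv[i] = vi;
    po[i] = pp[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  out.attr("dim") = p.attr("dim");
  return out;
}
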