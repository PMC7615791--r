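// [[Rcpp::depends(RcppArmadillo)]]
#pragma GCC optimize("O3,no-math-errno,tree-vectorize")
#pragma GCC target("avx2,fma")
#include <RcppArmadillo.h>
using namespace Rcpp;

// Forward pass of the N-subnetwork discriminator. `m_stack` holds nb
// subjects' N x p matrices stacked row-wise; subnetwork i consumes rows
// i, N+i, ... Hidden activations are returned node-major (rows
// (i-1)*nb .. i*nb-1 belong to subnetwork i) for the backward pass.
// [[Rcpp::export]]
List dis_fwd_cpp(const arma::mat& m_stack, const arma::cube& w1,
                 const arma::mat& b1, const arma::cube& w2,
                 const arma::mat& b2, const arma::mat& w3,
                 const arma::vec& b3, int nb) {
  const int n = w1.n_slices;
  const int p = w1.n_rows;
  const int h1 = w1.n_cols;
  const int h2 = w2.n_cols;
  arma::mat sig(nb, n);
  arma::mat a1s(static_cast<size_t>(n) * nb, h1);
  arma::mat a2s(static_cast<size_t>(n) * nb, h2);
  arma::mat x(nb, p);
  for (int i = 0; i < n; ++i) {
    for (int b = 0; b < nb; ++b) x.row(b) = m_stack.row(b * n + i);
    arma::mat a1 = x * w1.slice(i);
    a1.each_row() += b1.row(i);
    a1.transform([](double z) { return z > 0.0 ? z : 0.0; });
    arma::mat a2 = a1 * w2.slice(i);
    a2.each_row() += b2.row(i);
    a2.transform([](double z) { return z > 0.0 ? z : 0.0; });
    arma::vec z3 = a2 * w3.col(i) + b3(i);
    for (int b = 0; b < nb; ++b) sig(b, i) = 1.0 / (1.0 + std::exp(-z3(b)));
    a1s.rows(static_cast<size_t>(i) * nb, static_cast<size_t>(i + 1) * nb - 1) = a1;
    a2s.rows(static_cast<size_t>(i) * nb, static_cast<size_t>(i + 1) * nb - 1) = a2;
  }
  return List::create(Named("sig") = sig, Named("a1s") = a1s,
                      Named("a2s") = a2s);
}

// Backward pass: gradients wrt all subnetwork parameters and (optionally)
// the stacked input. ReLU masks are recovered from the stored activations.
// [[Rcpp::export]]
List dis_bwd_cpp(const arma::mat& dsig, const arma::mat& m_stack,
                 const arma::mat& sig, const arma::mat& a1s,
                 const arma::mat& a2s, const arma::cube& w1,
                 const arma::cube& w2, const arma::mat& w3, int nb,
                 bool need_dx) {
  const int n = w1.n_slices;
  const int p = w1.n_rows;
  const int h1 = w1.n_cols;
  const int h2 = w2.n_cols;
  arma::cube dw1(p, h1, n), dw2(h1, h2, n);
  arma::mat db1(n, h1), db2(n, h2), dw3(h2, n);
  arma::vec db3(n);
  arma::mat dx;
  if (need_dx) dx.zeros(m_stack.n_rows, p);
  arma::mat x(nb, p);
  for (int i = 0; i < n; ++i) {
    for (int b = 0; b < nb; ++b) x.row(b) = m_stack.row(b * n + i);
    const arma::mat a1 = a1s.rows(static_cast<size_t>(i) * nb,
                                  static_cast<size_t>(i + 1) * nb - 1);
    const arma::mat a2 = a2s.rows(static_cast<size_t>(i) * nb,
                                  static_cast<size_t>(i + 1) * nb - 1);
    arma::vec dz3(nb);
    for (int b = 0; b < nb; ++b) {
      double s = sig(b, i);
      dz3(b) = dsig(b, i) * s * (1.0 - s);
    }
    dw3.col(i) = a2.t() * dz3;
    db3(i) = arma::accu(dz3);
    arma::mat dz2 = dz3 * w3.col(i).t();
    dz2.elem(arma::find(a2 <= 0.0)).zeros();
    dw2.slice(i) = a1.t() * dz2;
    db2.row(i) = arma::sum(dz2, 0);
    arma::mat dz1 = dz2 * w2.slice(i).t();
    dz1.elem(arma::find(a1 <= 0.0)).zeros();
    dw1.slice(i) = x.t() * dz1;
    db1.row(i) = arma::sum(dz1, 0);
    if (need_dx) {
      arma::mat dxi = dz1 * w1.slice(i).t();
      for (int b = 0; b < nb; ++b) dx.row(b * n + i) = dxi.row(b);
    }
  }
  List out = List::create(Named("W1") = dw1, Named("b1") = db1,
                          Named("W2") = dw2, Named("b2") = db2,
                          Named("W3") = dw3, Named("b3") = db3);
  if (need_dx) out["dx"] = dx;
  return out;
}
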