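// [[Rcpp::depends(RcppArmadillo)]]
#pragma GCC optimize("O3,no-math-errno,tree-vectorize")
#pragma GCC target("avx2,fma")
#include <RcppArmadillo.h>
using namespace Rcpp;

// Row-wise affine-free layer normalization: y = (x - mean) / sqrt(var + eps)
// per row. Loops run column-outer to follow the column-major storage.
// Returns y and 1/sqrt(var + eps) for the backward pass.
// [[Rcpp::export]]
List layernorm_fwd_cpp(const arma::mat& x, double eps) {
  const int n = x.n_rows, d = x.n_cols;
  arma::mat y(n, d, arma::fill::none);
  arma::vec mu(n, arma::fill::zeros), v(n, arma::fill::zeros), inv(n);
  for (int j = 0; j < d; ++j) {
    const double* cx = x.colptr(j);
    for (int i = 0; i < n; ++i) mu(i) += cx[i];
  }
  mu /= d;
  for (int j = 0; j < d; ++j) {
    const double* cx = x.colptr(j);
    for (int i = 0; i < n; ++i) {
      double c = cx[i] - mu(i);
      v(i) += c * c;
    }
  }
  for (int i = 0; i < n; ++i) inv(i) = 1.0 / std::sqrt(v(i) / d + eps);
  for (int j = 0; j < d; ++j) {
    const double* cx = x.colptr(j);
    double* cy = y.colptr(j);
    for (int i = 0; i < n; ++i) cy[i] = (cx[i] - mu(i)) * inv(i);
  }
  return List::create(Named("y") = y, Named("inv") = inv);
}

// dx = inv * (dy - mean(dy) - y * mean(dy % y)) per row.
// [[Rcpp::export]]
arma::mat layernorm_bwd_cpp(const arma::mat& dy, const arma::mat& y,
                            const arma::vec& inv) {
  const int n = dy.n_rows, d = dy.n_cols;
  arma::mat dx(n, d, arma::fill::none);
  arma::vec m1(n, arma::fill::zeros), m2(n, arma::fill::zeros);
  for (int j = 0; j < d; ++j) {
    const double* cd = dy.colptr(j);
    const double* cy = y.colptr(j);
    for (int i = 0; i < n; ++i) {
      m1(i) += cd[i];
      m2(i) += cd[i] * cy[i];
    }
  }
  m1 /= d;
  m2 /= d;
  for (int j = 0; j < d; ++j) {
    const double* cd = dy.colptr(j);
    const double* cy = y.colptr(j);
    double* cdx = dx.colptr(j);
    for (int i = 0; i < n; ++i)
      cdx[i] = inv(i) * (cd[i] - m1(i) - cy[i] * m2(i));
  }
  return dx;
}
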