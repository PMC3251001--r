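// Single-precision design-matrix kernels.  The annealer's cost is dominated
// by two memory-bandwidth-bound products per iteration (S v and S^T a on an
// N x D stimulus matrix); storing S in float32 halves the traffic.  The
// products are accumulated and returned in double precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
SEXP design_build(const arma::mat& S) {
  arma::fmat* F = new arma::fmat(arma::conv_to<arma::fmat>::from(S));
  XPtr<arma::fmat> p(F, true);
  return p;
}

// [[Rcpp::export]]
NumericVector design_matvec(SEXP ptr, const arma::vec& v) {
  XPtr<arma::fmat> F(ptr);
  arma::fvec fv = arma::conv_to<arma::fvec>::from(v);
  arma::fvec r = (*F) * fv;
  return wrap(arma::conv_to<arma::vec>::from(r));
}

// [[Rcpp::export]]
NumericVector design_crossvec(SEXP ptr, const arma::vec& a) {
  XPtr<arma::fmat> F(ptr);
  arma::fvec fa = arma::conv_to<arma::fvec>::from(a);
  arma::fvec r = F->t() * fa;
  return wrap(arma::conv_to<arma::vec>::from(r));
}

// [[Rcpp::export]]
NumericVector design_row(SEXP ptr, int i) {
  XPtr<arma::fmat> F(ptr);
  arma::frowvec r = F->row(i - 1);
  return wrap(arma::conv_to<arma::rowvec>::from(r));
}

// [[Rcpp::export]]
IntegerVector design_dim(SEXP ptr) {
  XPtr<arma::fmat> F(ptr);
  return IntegerVector::create(F->n_rows, F->n_cols);
}

// [[Rcpp::export]]
arma::mat design_gram(SEXP ptr) {
  XPtr<arma::fmat> F(ptr);
  arma::fmat G = F->t() * (*F);
  return arma::conv_to<arma::mat>::from(G);
}

// [[Rcpp::export]]
arma::mat design_gram_weighted(SEXP ptr, const arma::vec& w) {
  XPtr<arma::fmat> F(ptr);
  arma::fvec fw = arma::conv_to<arma::fvec>::from(w);
  arma::fmat Fw = *F;
  Fw.each_col() %= fw;
  arma::fmat G = F->t() * Fw;
  return arma::conv_to<arma::mat>::from(G);
}
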