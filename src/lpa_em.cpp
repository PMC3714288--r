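// EM inner loop for the Gaussian latent profile model under local
// independence, with full-information handling of missing cells: the
// E-step density product runs over observed cells only (mask = 1).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Per-class log-density matrix (n x K): sum over observed cells of the
// univariate normal log-density. x0 has missing cells zeroed; mask is 0/1.
// [[Rcpp::export]]
arma::mat lpa_logdens_cpp(const arma::mat& x0, const arma::mat& mask,
                          const arma::mat& mu, const arma::mat& s2) {
  const uword n = x0.n_rows, K = mu.n_rows;
  mat out(n, K);
  for (uword k = 0; k < K; ++k) {
    rowvec s2k = s2.row(k);
    rowvec cst = -0.5 * log(2.0 * datum::pi * s2k);
    mat dev = x0.each_row() - mu.row(k);
    mat dev2 = dev % dev % mask;
    out.col(k) = mask * cst.t() + dev2 * (-0.5 / s2k.t());
  }
  return out;
}

static double estep(const mat& x0, const mat& mask, const rowvec& pi_k,
                    const mat& mu, const mat& s2, mat& post) {
  mat lg = lpa_logdens_cpp(x0, mask, mu, s2);
  lg.each_row() += log(pi_k);
  vec m = max(lg, 1);
  vec lse = m + log(sum(exp(lg.each_col() - m), 1));
  lse(find_nonfinite(m)).fill(-datum::inf);
  post = exp(lg.each_col() - lse);
  return accu(lse);
}

// One EM run from given starting values. Returns the parameter estimates,
// the log-likelihood recomputed at the returned parameters, and flags for
// convergence (loglik gain < tol) and component collapse (pi < 1e-6).
// [[Rcpp::export]]
Rcpp::List lpa_em_cpp(const arma::mat& x0, const arma::mat& mask,
                      arma::rowvec pi_k, arma::mat mu, arma::mat s2,
                      const bool invariant, const double tol,
                      const int max_iter) {
  const uword p = x0.n_cols, K = pi_k.n_elem;
  double ll = -datum::inf, ll_old = -datum::inf;
  bool converged = false, empty = false;
  mat post;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    ll = estep(x0, mask, pi_k, mu, s2, post);
    pi_k = mean(post, 0);
    if (pi_k.min() < 1e-6) { empty = true; break; }
    for (uword k = 0; k < K; ++k) {
      rowvec wobs = post.col(k).t() * mask;
      mu.row(k) = (post.col(k).t() * x0) / clamp(wobs, 1e-8, datum::inf);
    }
    if (invariant) {
      rowvec num(p, fill::zeros), den(p, fill::zeros);
      for (uword k = 0; k < K; ++k) {
        mat dev = x0.each_row() - mu.row(k);
        num += post.col(k).t() * (dev % dev % mask);
        den += post.col(k).t() * mask;
      }
      rowvec s2row = clamp(num / clamp(den, 1e-8, datum::inf),
                           1e-8, datum::inf);
      s2.each_row() = s2row;
    } else {
      for (uword k = 0; k < K; ++k) {
        mat dev = x0.each_row() - mu.row(k);
        rowvec wobs = post.col(k).t() * mask;
        s2.row(k) = clamp((post.col(k).t() * (dev % dev % mask)) /
                            clamp(wobs, 1e-8, datum::inf),
                          1e-8, datum::inf);
      }
    }
    if (std::isfinite(ll_old) && ll - ll_old < tol) {
      converged = true;
      break;
    }
    ll_old = ll;
  }
  if (!empty) {
    ll = estep(x0, mask, pi_k, mu, s2, post);  // loglik at final params
  }
  return Rcpp::List::create(
      Rcpp::Named("pi") = pi_k, Rcpp::Named("mu") = mu,
      Rcpp::Named("sigma2") = s2, Rcpp::Named("loglik") = ll,
      Rcpp::Named("iter") = iter, Rcpp::Named("converged") = converged,
      Rcpp::Named("empty") = empty);
}
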