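// Scaled forward-backward recursions for a hidden Markov chain.
// Works from per-sample state log-densities so that long recordings
// (>= 1e5 samples) do not underflow.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// logB: K x T state log-densities; A: K x K transition matrix; pi: K
// returns gamma (K x T), xi (K x K expected transition counts summed
// over time) and the sequence log-likelihood.
// [[Rcpp::export(name = ".forwardBackwardC")]]
List forwardBackwardC(const arma::mat& logB, const arma::mat& A,
                      const arma::vec& pi) {
  const arma::uword K = logB.n_rows, T = logB.n_cols;
  arma::mat alpha(K, T), beta(K, T), b(K, T);
  arma::vec c(T), mx(T);

  for (arma::uword t = 0; t < T; ++t) {
    mx(t) = logB.col(t).max();
    b.col(t) = arma::exp(logB.col(t) - mx(t));
  }

  alpha.col(0) = pi % b.col(0);
  c(0) = arma::accu(alpha.col(0));
  alpha.col(0) /= c(0);
  for (arma::uword t = 1; t < T; ++t) {
    alpha.col(t) = (A.t() * alpha.col(t - 1)) % b.col(t);
    c(t) = arma::accu(alpha.col(t));
    alpha.col(t) /= c(t);
  }

  beta.col(T - 1).ones();
  for (arma::uword t = T - 1; t > 0; --t) {
    beta.col(t - 1) = A * (b.col(t) % beta.col(t)) / c(t);
  }

  arma::mat gamma = alpha % beta;
  gamma.each_row() /= arma::sum(gamma, 0);  // guard tiny rounding drift

  arma::mat xi(K, K, arma::fill::zeros);
  for (arma::uword t = 0; t + 1 < T; ++t) {
    xi += (A % (alpha.col(t) * (b.col(t + 1) % beta.col(t + 1)).t())) / c(t + 1);
  }

  double loglik = arma::accu(arma::log(c)) + arma::accu(mx);
  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}
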