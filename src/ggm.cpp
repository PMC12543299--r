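// Gibbs kernels for the spike-and-slab Gaussian graphical model.
// All randomness goes through R's RNG (norm_rand/unif_rand/R::rgamma) so
// draws are reproducible from .Random.seed and respect RNG substreams.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Bernoulli update of all edge indicators given the current precision
// matrix: log-odds = log N(w; 0, v1^2) - log N(w; 0, v0^2) + prior_logodds.
// pairs0: E x 2 matrix of 0-based node pairs in lexicographic order.
// [[Rcpp::export]]
arma::ivec sample_edge_indicators_cpp(const arma::mat& Omega,
                                      const arma::imat& pairs0,
                                      double v0, double v1,
                                      const arma::vec& prior_logodds) {
  const int E = pairs0.n_rows;
  arma::ivec gamma(E);
  for (int e = 0; e < E; ++e) {
    const double w = Omega(pairs0(e, 0), pairs0(e, 1));
    double lo = R::dnorm(w, 0.0, v1, 1) - R::dnorm(w, 0.0, v0, 1) +
                prior_logodds(e);
    if (lo > 700.0) lo = 700.0;
    if (lo < -700.0) lo = -700.0;
    const double p = 1.0 / (1.0 + std::exp(-lo));
    gamma(e) = (unif_rand() < p) ? 1 : 0;
  }
  return gamma;
}

static void update_column(arma::mat& Omega, const arma::ivec& gamma,
                          const arma::mat& U, double Tn,
                          double v0, double v1, double lambda,
                          int j, const arma::imat& eid) {
  const int P = Omega.n_rows;
  arma::uvec idx(P - 1);
  int k = 0;
  for (int i = 0; i < P; ++i)
    if (i != j) idx(k++) = i;

  arma::mat Om11 = Omega.submat(idx, idx);
  arma::mat Om11inv;
  if (!arma::inv_sympd(Om11inv, Om11))
    stop("precision update failed: Omega[-j,-j] not positive definite at column %d",
         j + 1);

  // spike/slab prior precisions for the edges incident to j
  arma::vec dinv(P - 1);
  for (int m = 0; m < P - 1; ++m) {
    const int e = eid(idx(m), j);
    const double v = gamma(e) ? v1 : v0;
    dinv(m) = 1.0 / (v * v);
  }

  const double ujj_l = U(j, j) + lambda;
  arma::mat Cinv = ujj_l * Om11inv;
  Cinv.diag() += dinv;
  arma::mat R;
  if (!arma::chol(R, Cinv))
    stop("precision update failed: proposal precision not positive definite at column %d",
         j + 1);

  arma::vec b(P - 1);
  for (int m = 0; m < P - 1; ++m) b(m) = -U(idx(m), j);
  // mean = Cinv^{-1} b via the Cholesky factor
  arma::vec mean = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), b));
  arma::vec z(P - 1);
  for (int m = 0; m < P - 1; ++m) z(m) = norm_rand();
  arma::vec u = mean + arma::solve(arma::trimatu(R), z);

  const double g = R::rgamma(1.0 + Tn / 2.0, 2.0 / ujj_l);  // shape, scale

  for (int m = 0; m < P - 1; ++m) {
    Omega(idx(m), j) = u(m);
    Omega(j, idx(m)) = u(m);
  }
  Omega(j, j) = g + arma::as_scalar(u.t() * Om11inv * u);
}

// One column update (exported for targeted tests); j1 is 1-based.
// [[Rcpp::export]]
arma::mat sample_precision_column_cpp(arma::mat Omega, const arma::ivec& gamma,
                                      const arma::mat& U, double Tn,
                                      double v0, double v1, double lambda,
                                      int j1, const arma::imat& eid) {
  update_column(Omega, gamma, U, Tn, v0, v1, lambda, j1 - 1, eid);
  return Omega;
}

// Full sweeps: indicator update, then columns 1..P in order.
// [[Rcpp::export]]
List ggm_sweep_cpp(arma::mat Omega, arma::ivec gamma, const arma::mat& U,
                   double Tn, double v0, double v1, double lambda,
                   const arma::vec& prior_logodds, const arma::imat& pairs0,
                   const arma::imat& eid, int n_sweeps) {
  const int P = Omega.n_rows;
  for (int s = 0; s < n_sweeps; ++s) {
    gamma = sample_edge_indicators_cpp(Omega, pairs0, v0, v1, prior_logodds);
    for (int j = 0; j < P; ++j)
      update_column(Omega, gamma, U, Tn, v0, v1, lambda, j, eid);
  }
  return List::create(_["Omega"] = Omega, _["gamma"] = gamma);
}
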