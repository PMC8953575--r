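#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Standard normal truncated to (a, Inf). Naive rejection for small a,
// Robert (1995) translated-exponential rejection otherwise; both use R's RNG
// so set.seed() governs the whole chain.
static double rtnorm_lower(double a) {
  if (a < 0.45) {
    double x;
    do {
      x = norm_rand();
    } while (x <= a);
    return x;
  }
  double lam = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a - std::log(unif_rand()) / lam;
    double d = x - lam;
    if (std::log(unif_rand()) <= -0.5 * d * d) return x;
  }
}

// Gibbs sampler for probit regression with independent normal priors.
// Latent z_i ~ N(x_i' theta, 1) truncated by the observed outcome; the
// conditional for theta is N(m, (X'X + P0)^{-1}) with P0 the prior precision.
// [[Rcpp::export]]
arma::mat gibbs_probit_cpp(const arma::mat& X, const arma::ivec& y,
                           const arma::vec& prior_mean,
                           const arma::vec& prior_var,
                           int iterations, int burn_in) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec prec = 1.0 / prior_var;
  arma::mat P = X.t() * X;
  P.diag() += prec;
  arma::mat R = arma::chol(P);  // R'R = posterior precision (constant)
  arma::vec b0 = prec % prior_mean;
  arma::vec theta = prior_mean;
  arma::mat out(iterations - burn_in, p);
  arma::vec z(n), eta(p);
  for (int it = 0; it < iterations; ++it) {
    arma::vec mu = X * theta;
    for (int i = 0; i < n; ++i) {
      if (y[i] == 1)
        z[i] = mu[i] + rtnorm_lower(-mu[i]);
      else
        z[i] = mu[i] - rtnorm_lower(mu[i]);
    }
    arma::vec b = X.t() * z + b0;
    arma::vec m =
        arma::solve(arma::trimatu(R), arma::solve(arma::trimatl(R.t()), b));
    for (int j = 0; j < p; ++j) eta[j] = norm_rand();
    theta = m + arma::solve(arma::trimatu(R), eta);
    if (it >= burn_in) out.row(it - burn_in) = theta.t();
  }
  return out;
}
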