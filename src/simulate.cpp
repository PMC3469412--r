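#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Closed-form solution of dc/dt = A c via the matrix exponential,
// evaluated at each requested time. times[0] is t0; the first column of
// the result is c0 exactly.
// [[Rcpp::export(name = ".sim_expm")]]
arma::mat sim_expm(const arma::mat& A, const arma::vec& c0,
                   const arma::vec& times) {
  const arma::uword K = A.n_rows, T = times.n_elem;
  arma::mat out(K, T);
  out.col(0) = c0;
  const double t0 = times[0];
  for (arma::uword j = 1; j < T; ++j) {
    out.col(j) = arma::expmat(A * (times[j] - t0)) * c0;
  }
  return out;
}

// Gene-count-weighted mean of per-cluster Pearson correlations between
// simulated and observed trajectories. A constant vector on either side
// contributes correlation 0 for that cluster.
// [[Rcpp::export(name = ".weighted_cor")]]
double weighted_cor(const arma::mat& sim, const arma::mat& obs,
                    const arma::vec& w) {
  const arma::uword K = sim.n_rows;
  double num = 0.0, den = 0.0;
  for (arma::uword i = 0; i < K; ++i) {
    arma::rowvec x = sim.row(i), y = obs.row(i);
    const double mx = arma::mean(x), my = arma::mean(y);
    x -= mx; y -= my;
    const double sx = arma::norm(x, 2), sy = arma::norm(y, 2);
    double r = 0.0;
    if (sx > 0.0 && sy > 0.0) r = arma::dot(x, y) / (sx * sy);
    num += w[i] * r;
    den += w[i];
  }
  return num / den;
}

// Fitness of an influence matrix against one observed course: simulate
// from the first observed state, then weighted correlation. One call per
// annealing step, so the whole evaluation stays on the C++ side.
// [[Rcpp::export(name = ".sim_fitness")]]
double sim_fitness(const arma::mat& A, const arma::vec& times,
                   const arma::mat& obs, const arma::vec& w) {
  arma::mat sim = sim_expm(A, obs.col(0), times);
  return weighted_cor(sim, obs, w);
}
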