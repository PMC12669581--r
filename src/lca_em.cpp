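// EM core for the latent class model. The E-step is a dense product of the
// one-hot design with the stacked log item-response matrix; the M-step
// renormalizes expected counts within item blocks with a probability floor.
// Randomness (Dirichlet posterior initialization) draws from R's RNG so
// fits are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double RHO_FLOOR = 1e-6;

// M-step: counts -> (pi, rho) with per-item flooring and renormalization
static void mstep(const arma::mat& oh, const arma::mat& tau,
                  const arma::uvec& item, int J,
                  arma::vec& pi, arma::mat& rho) {
  const int n = oh.n_rows, K = tau.n_cols, M = oh.n_cols;
  pi = arma::sum(tau, 0).t() / (double)n;
  rho = oh.t() * tau;                       // M x K expected counts
  arma::mat tot(J, K, arma::fill::zeros);
  for (int m = 0; m < M; ++m) tot.row(item[m]) += rho.row(m);
  for (int m = 0; m < M; ++m)
    for (int k = 0; k < K; ++k) {
      double t = tot(item[m], k);
      rho(m, k) = (t > 0) ? rho(m, k) / t : 0.0;
      if (rho(m, k) < RHO_FLOOR) rho(m, k) = RHO_FLOOR;
    }
  // renormalize after flooring
  tot.zeros();
  for (int m = 0; m < M; ++m) tot.row(item[m]) += rho.row(m);
  for (int m = 0; m < M; ++m)
    for (int k = 0; k < K; ++k) rho(m, k) /= tot(item[m], k);
}

// E-step: returns loglik, fills tau
static double estep(const arma::mat& oh, const arma::vec& log_pi,
                    const arma::mat& log_rho, arma::mat& tau) {
  tau = oh * log_rho;                       // n x K class log-joints
  tau.each_row() += log_pi.t();
  double ll = 0.0;
  for (arma::uword i = 0; i < tau.n_rows; ++i) {
    double mx = tau.row(i).max();
    double s = 0.0;
    for (arma::uword k = 0; k < tau.n_cols; ++k)
      s += std::exp(tau(i, k) - mx);
    double lse = mx + std::log(s);
    ll += lse;
    for (arma::uword k = 0; k < tau.n_cols; ++k)
      tau(i, k) = std::exp(tau(i, k) - lse);
  }
  return ll;
}

// [[Rcpp::export]]
List lca_em_multistart(const arma::mat& oh, const arma::uvec& item_index,
                       int n_items, int K, int n_starts, int max_iter,
                       double tol) {
  RNGScope scope;
  const int n = oh.n_rows;
  arma::uvec item = item_index - 1;          // to 0-based

  double best_ll = -arma::datum::inf;
  arma::vec best_pi;
  arma::mat best_rho, best_tau;
  bool best_conv = false;
  int best_iter = 0;
  std::vector<double> best_trace;

  for (int s = 0; s < n_starts; ++s) {
    // Dirichlet(1) posterior rows via R's gamma draws (column-major order,
    // matching matrix(rgamma(n*K, 1), n, K))
    arma::mat tau(n, K);
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < n; ++i) tau(i, k) = R::rgamma(1.0, 1.0);
    tau.each_col() /= arma::sum(tau, 1);

    arma::vec pi;
    arma::mat rho;
    mstep(oh, tau, item, n_items, pi, rho);

    double ll_old = -arma::datum::inf, ll = 0.0;
    bool converged = false;
    int iter = 0;
    std::vector<double> trace;
    while (true) {
      ++iter;
      ll = estep(oh, arma::log(pi), arma::log(rho), tau);
      trace.push_back(ll);
      if (iter > 1 && ll - ll_old < tol) { converged = true; break; }
      if (iter >= max_iter) break;
      ll_old = ll;
      mstep(oh, tau, item, n_items, pi, rho);
    }
    if (ll > best_ll) {
      best_ll = ll; best_pi = pi; best_rho = rho; best_tau = tau;
      best_conv = converged; best_iter = iter; best_trace = trace;
    }
  }

  return List::create(
    _["pi"] = best_pi, _["rho"] = best_rho, _["tau"] = best_tau,
    _["loglik"] = best_ll, _["converged"] = best_conv,
    _["n_iterations"] = best_iter,
    _["trace"] = NumericVector(best_trace.begin(), best_trace.end()));
}
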