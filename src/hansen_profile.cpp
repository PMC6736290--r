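// Profile log-likelihood of the Hansen model for one trait at a given
// selection strength alpha: regime optima by GLS, sigma2 at its ML value.
// Covariance V0 is the unit-rate OU covariance (Brownian s-matrix in the
// alpha -> 0 limit); W is the regime-exposure design built from the
// tip-by-edge path incidence matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List hansen_profile_cpp(const arma::mat &s, const arma::mat &d,
                              double height, const arma::mat &incidence,
                              const arma::vec &edge_t0, const arma::vec &edge_t1,
                              const arma::ivec &edge_regime, int K, int bcol,
                              double alpha, const arma::vec &y) {
  const uword n = s.n_rows;
  mat V0;
  if (alpha * height < 1e-8) {
    V0 = s;
  } else {
    V0 = exp(-alpha * d) % (1.0 - exp(-2.0 * alpha * s)) / (2.0 * alpha);
  }
  mat L;
  if (!chol(L, symmatu(V0), "lower"))
    return Rcpp::List::create(Rcpp::Named("ok") = false);

  const uword E = edge_t0.n_elem;
  mat A(E, (uword)K, fill::zeros);
  for (uword e = 0; e < E; ++e) {
    double a = std::exp(-alpha * (height - edge_t1(e))) -
               std::exp(-alpha * (height - edge_t0(e)));
    A(e, (uword)(edge_regime(e) - 1)) += a;
  }
  mat W = incidence * A;
  W.col((uword)(bcol - 1)) += std::exp(-alpha * height);

  mat Wst = solve(trimatl(L), W);
  vec yst = solve(trimatl(L), y);
  mat Qm, Rm;
  if (!qr_econ(Qm, Rm, Wst))
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  double rmax = max(abs(Rm.diag()));
  if (rmax <= 0 || min(abs(Rm.diag())) < 1e-10 * rmax)
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  vec theta = solve(trimatu(Rm), Qm.t() * yst);
  vec resid = yst - Wst * theta;
  double rss = dot(resid, resid);
  double sigma2 = std::max(rss / (double)n, 1e-12);
  double lnL = -0.5 * (double)n * (std::log(2.0 * M_PI * sigma2) + 1.0) -
               sum(log(L.diag()));
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("lnL") = lnL,
                            Rcpp::Named("theta") = theta,
                            Rcpp::Named("sigma2") = sigma2);
}
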