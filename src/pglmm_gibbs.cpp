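// Blocked Gibbs sampler for the multivariate phylogenetic mixed model
// (animal model with the phylogeny's relatedness matrix A as pedigree):
//
//   vec(Y) = (I_m (x) X) beta + u + e,  u ~ N(0, G (x) A),  e ~ N(0, R (x) I_n)
//
// The sampler works in the eigenbasis of A (A = U D U'): rows of the rotated
// data are independent with covariance d_i * G + R. A generalized
// eigendecomposition of (G, R) (R = L L', L^-1 G L^-T = Q Lam Q') turns every
// per-species covariance into K diag(d_i*lam + 1) K' with K = L^-T Q, so all
// per-species updates are O(m^2). beta is drawn from its full conditional
// with u integrated out (exact blocked scheme, equivalent to the joint
// (beta, u) draw from the mixed-model equations), then u | beta, then
// conjugate inverse-Wishart updates for G and R. Uses R's RNG so set.seed()
// governs reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Wishart(df, S) via Bartlett decomposition; chol_S = chol(S, "lower")
static mat rwishart_chol(double df, const mat &chol_S) {
  const uword m = chol_S.n_rows;
  mat A(m, m, fill::zeros);
  for (uword i = 0; i < m; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat L = chol_S * A;
  return L * L.t();
}

// Inverse-Wishart(df, S): if W ~ Wishart(df, S^-1) then W^-1 ~ IW(df, S)
static mat rinvwishart(double df, const mat &S) {
  mat Sinv = inv_sympd(symmatu(S));
  mat W = rwishart_chol(df, chol(symmatu(Sinv), "lower"));
  return inv_sympd(symmatu(W));
}

static vec rnorm_vec(uword k) {
  vec z(k);
  for (uword i = 0; i < k; ++i) z(i) = R::norm_rand();
  return z;
}

static vec vech_col(const mat &M) {
  const uword m = M.n_rows;
  vec v(m * (m + 1) / 2);
  uword k = 0;
  for (uword j = 0; j < m; ++j)
    for (uword i = j; i < m; ++i) v(k++) = M(i, j);
  return v;
}

// [[Rcpp::export]]
Rcpp::List pglmm_gibbs_cpp(const arma::mat &Y, const arma::mat &X,
                           const arma::vec &d,
                           double nu_G, const arma::mat &S_G,
                           double nu_R, const arma::mat &S_R,
                           int n_iter, int burnin, int thin) {
  const uword n = Y.n_rows, m = Y.n_cols, p = X.n_cols;
  const uword nstore = (uword)((n_iter - burnin) / thin);
  const uword nv = m * (m + 1) / 2;

  mat G = symmatu(S_G), R = symmatu(S_R);
  mat B(p, m, fill::zeros);
  mat U(n, m, fill::zeros);

  mat Gs(nstore, nv), Rs(nstore, nv), Bs(nstore, p * m);
  vec devs(nstore);
  uword s = 0;

  std::vector<mat> xouter(n);
  for (uword i = 0; i < n; ++i) xouter[i] = X.row(i).t() * X.row(i);

  for (int it = 1; it <= n_iter; ++it) {
    // generalized eigendecomposition of (G, R)
    mat LR = chol(symmatu(R), "lower");
    mat M = solve(trimatl(LR), solve(trimatl(LR), symmatu(G)).t());
    vec lam; mat Q;
    eig_sym(lam, Q, symmatu(M));
    lam = clamp(lam, 1e-12, datum::inf);
    mat K = solve(trimatu(LR.t()), Q);   // K = L^-T Q, so K W K' with diag W
    mat Kinv_t = LR * Q;                 // K^-T = L Q

    // ---- beta | G, R, Y (u integrated out) ----
    // Sigma_i^-1 = sum_j w_ij k_j k_j', w_ij = 1/(d_i lam_j + 1)
    mat Yk = Y * K;                      // row i = K' y_i
    mat Wgt(n, m);
    for (uword i = 0; i < n; ++i)
      for (uword j = 0; j < m; ++j) Wgt(i, j) = 1.0 / (d(i) * lam(j) + 1.0);
    mat P(m * p, m * p, fill::zeros);
    vec r(m * p, fill::zeros);
    {
      std::vector<mat> Aj(m, mat(p, p, fill::zeros));
      for (uword i = 0; i < n; ++i)
        for (uword j = 0; j < m; ++j) Aj[j] += Wgt(i, j) * xouter[i];
      mat Pk(m * p, m * p, fill::zeros);  // in K-eigen coordinates
      for (uword j = 0; j < m; ++j)
        Pk.submat(j * p, j * p, (j + 1) * p - 1, (j + 1) * p - 1) = Aj[j];
      mat Km = kron(K, eye(p, p));
      P = Km * Pk * Km.t();
      for (uword i = 0; i < n; ++i) {
        vec w = K * (Wgt.row(i).t() % Yk.row(i).t());  // Sigma_i^-1 y_i
        r += kron(w, X.row(i).t());
      }
    }
    mat Pc = chol(symmatu(P));
    vec mu_b = solve(symmatu(P), r, solve_opts::likely_sympd);
    vec b = mu_b + solve(trimatu(Pc), rnorm_vec(m * p));
    B = reshape(b, p, m);

    // ---- u_i | beta, G, R ----
    // precision K D_i K', D_i = diag(1/(d_i lam_j) + 1);
    // mean = K^-T D_i^-1 K' resid_i, draw = mean + K^-T D_i^-1/2 z
    mat resid = Y - X * B;
    mat Rk = resid * K;                  // row i = K' resid_i
    mat Su(m, m, fill::zeros), Se(m, m, fill::zeros);
    for (uword i = 0; i < n; ++i) {
      vec Dinv(m);
      for (uword j = 0; j < m; ++j)
        Dinv(j) = 1.0 / (1.0 / (d(i) * lam(j)) + 1.0);
      vec ui = Kinv_t * (Dinv % Rk.row(i).t() + sqrt(Dinv) % rnorm_vec(m));
      U.row(i) = ui.t();
      Su += ui * ui.t() / d(i);
      vec ei = resid.row(i).t() - ui;
      Se += ei * ei.t();
    }

    // ---- conjugate inverse-Wishart updates ----
    G = rinvwishart(nu_G + (double)n, symmatu(S_G + Su));
    R = rinvwishart(nu_R + (double)n, symmatu(S_R + Se));

    if (it > burnin && (it - burnin) % thin == 0 && s < nstore) {
      // deviance of y | beta, G, R at the stored parameter state
      mat LR2 = chol(symmatu(R), "lower");
      mat M2 = solve(trimatl(LR2), solve(trimatl(LR2), symmatu(G)).t());
      vec lam2; mat Q2;
      eig_sym(lam2, Q2, symmatu(M2));
      lam2 = clamp(lam2, 1e-12, datum::inf);
      mat K2 = solve(trimatu(LR2.t()), Q2);
      mat Rk2 = (Y - X * B) * K2;
      double logdetR2 = 2.0 * sum(log(LR2.diag()));
      double dev = 0.0;
      for (uword i = 0; i < n; ++i) {
        double ld = logdetR2, qf = 0.0;
        for (uword j = 0; j < m; ++j) {
          ld += std::log(d(i) * lam2(j) + 1.0);
          qf += Rk2(i, j) * Rk2(i, j) / (d(i) * lam2(j) + 1.0);
        }
        dev += m * std::log(2.0 * M_PI) + ld + qf;
      }
      Gs.row(s) = vech_col(G).t();
      Rs.row(s) = vech_col(R).t();
      Bs.row(s) = vectorise(B).t();
      devs(s) = dev;
      ++s;
    }
  }

  return Rcpp::List::create(Rcpp::Named("G") = Gs, Rcpp::Named("R") = Rs,
                            Rcpp::Named("beta") = Bs,
                            Rcpp::Named("deviance") = devs);
}
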