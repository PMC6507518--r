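#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Marginal weighted log-likelihood machinery for the two-arm random
// coefficient model.  Per cluster k the marginal covariance is
//   V_k = Z_k Omega Z_k' + sigma_eps^2 * diag(1 / w_ik),
// with Z_k = [t, 1 - t] mapping onto (b_k1, b_k0) and
//   Omega = [[s1sq, rho*s1*s0], [rho*s1*s0, s0sq]].
// Because Z has indicator columns, Z' D^{-1} Z is diagonal and every
// per-cluster quantity reduces to 2x2 algebra (Woodbury / determinant
// lemma):
//   V^{-1} = D^{-1} - D^{-1} Z Omega (I + C Omega)^{-1} Z' D^{-1},
//   det V  = det D * det(I + C Omega),  C = Z' D^{-1} Z,
// which stays valid when Omega is singular (sigma0 = sigma1 = 0).
//
// The likelihood touches the data only through per-cluster sufficient
// statistics that do not depend on the variance components (the unit
// weights are fixed): treated/control weight sums, X' diag(w) X,
// X' diag(w) y, the weighted y sums per arm, sum w y^2, sum log w and
// n_k.  These are computed once (hlm_suffstats) so that each likelihood
// evaluation is O(K) small-matrix work, independent of N.

// [[Rcpp::export(name = ".hlm_suffstats")]]
List hlm_suffstats(const arma::vec& y, const arma::vec& t,
                   const arma::vec& w, const arma::mat& X,
                   const arma::uvec& start, const arma::uvec& nk) {
  const arma::uword K = start.n_elem;
  const arma::uword p = X.n_cols;
  arma::vec sw1(K), sw0(K), uy1(K), uy0(K), yWy(K), slogw(K);
  arma::mat Xwt(p, K), Xwc(p, K), XtWy(p, K);
  arma::cube XtWX(p, p, K);
  for (arma::uword k = 0; k < K; ++k) {
    const arma::uword a = start(k), n = nk(k);
    const arma::vec yk = y.subvec(a, a + n - 1);
    const arma::vec tk = t.subvec(a, a + n - 1);
    const arma::vec wk = w.subvec(a, a + n - 1);
    const arma::mat Xk = X.rows(a, a + n - 1);
    const arma::vec w1 = wk % tk, w0 = wk - w1;
    sw1(k) = arma::accu(w1);
    sw0(k) = arma::accu(w0);
    uy1(k) = arma::dot(w1, yk);
    uy0(k) = arma::dot(w0, yk);
    yWy(k) = arma::dot(wk, yk % yk);
    slogw(k) = arma::accu(arma::log(wk));
    Xwt.col(k) = Xk.t() * w1;
    Xwc.col(k) = Xk.t() * w0;
    XtWy.col(k) = Xk.t() * (wk % yk);
    XtWX.slice(k) = Xk.t() * (Xk.each_col() % wk);
  }
  return List::create(
    Named("K") = (int)K, Named("p") = (int)p,
    Named("nk") = nk, Named("sw1") = sw1, Named("sw0") = sw0,
    Named("uy1") = uy1, Named("uy0") = uy0, Named("yWy") = yWy,
    Named("slogw") = slogw, Named("Xwt") = Xwt, Named("Xwc") = Xwc,
    Named("XtWy") = XtWy, Named("XtWX") = XtWX);
}

// [[Rcpp::export(name = ".hlm_core")]]
List hlm_core(const List& ss, const arma::vec& vk,
              double s1sq, double s0sq, double rho, double sesq,
              bool profile_beta, const arma::vec& beta_in,
              bool want_blups, bool want_scores) {
  if (sesq <= 0.0) stop("sigma_eps_sq must be strictly positive");
  const int K = ss["K"], p = ss["p"];
  const arma::uvec nk = ss["nk"];
  const arma::vec sw1 = ss["sw1"], sw0 = ss["sw0"];
  const arma::vec uy1 = ss["uy1"], uy0 = ss["uy0"];
  const arma::vec yWy = ss["yWy"], slogw = ss["slogw"];
  const arma::mat Xwt = ss["Xwt"], Xwc = ss["Xwc"], XtWy = ss["XtWy"];
  const arma::cube XtWX = ss["XtWX"];

  arma::mat Omega(2, 2);
  Omega(0, 0) = s1sq;
  Omega(1, 1) = s0sq;
  Omega(0, 1) = Omega(1, 0) = rho * std::sqrt(s1sq * s0sq);

  arma::mat A(p, p, arma::fill::zeros);       // sum_k v_k X'V^{-1}X
  arma::mat bread(p, p, arma::fill::zeros);   // sum_k X'V^{-1}X (no v)
  arma::vec bvec(p, arma::fill::zeros);       // sum_k v_k X'V^{-1}y
  double Syy = 0.0, logdet = 0.0, nlog2pi = 0.0;
  const double log2pi = std::log(2.0 * M_PI);
  const double inv_se = 1.0 / sesq;

  // per-cluster 2x2 pieces kept for the second (blup/score) pass
  arma::mat G_all(4, K);
  arma::mat Ux(p, 2), XtViX(p, p);
  arma::vec uy(2), XtViy(p);

  for (int k = 0; k < K; ++k) {
    // C = Z'D^{-1}Z = diag(sw1, sw0)/sesq ; M2 = I + C Omega
    const double c1 = sw1(k) * inv_se, c0 = sw0(k) * inv_se;
    const double m11 = 1.0 + c1 * Omega(0, 0), m12 = c1 * Omega(0, 1);
    const double m21 = c0 * Omega(1, 0), m22 = 1.0 + c0 * Omega(1, 1);
    const double detM2 = m11 * m22 - m12 * m21;
    if (!(detM2 > 0.0)) stop("singular per-cluster covariance");
    // G = Omega (I + C Omega)^{-1}, symmetrized
    const double i11 = m22 / detM2, i12 = -m12 / detM2;
    const double i21 = -m21 / detM2, i22 = m11 / detM2;
    double g11 = Omega(0, 0) * i11 + Omega(0, 1) * i21;
    double g12 = Omega(0, 0) * i12 + Omega(0, 1) * i22;
    double g21 = Omega(1, 0) * i11 + Omega(1, 1) * i21;
    double g22 = Omega(1, 0) * i12 + Omega(1, 1) * i22;
    const double goff = 0.5 * (g12 + g21);
    g12 = g21 = goff;
    G_all(0, k) = g11; G_all(1, k) = g21; G_all(2, k) = g12;
    G_all(3, k) = g22;

    uy(0) = uy1(k) * inv_se;
    uy(1) = uy0(k) * inv_se;
    Ux.col(0) = Xwt.col(k) * inv_se;
    Ux.col(1) = Xwc.col(k) * inv_se;

    // X'V^{-1}X = X'D^{-1}X - Ux G Ux'
    const arma::vec gu0 = g11 * Ux.col(0) + g12 * Ux.col(1);
    const arma::vec gu1 = g21 * Ux.col(0) + g22 * Ux.col(1);
    XtViX = XtWX.slice(k) * inv_se;
    XtViX -= Ux.col(0) * gu0.t() + Ux.col(1) * gu1.t();
    const double guy0 = g11 * uy(0) + g12 * uy(1);
    const double guy1 = g21 * uy(0) + g22 * uy(1);
    XtViy = XtWy.col(k) * inv_se - Ux.col(0) * guy0 - Ux.col(1) * guy1;
    const double yViy = yWy(k) * inv_se - (uy(0) * guy0 + uy(1) * guy1);
    const double ld = nk(k) * std::log(sesq) - slogw(k) + std::log(detM2);

    A += vk(k) * XtViX;
    bread += XtViX;
    bvec += vk(k) * XtViy;
    Syy += vk(k) * yViy;
    logdet += vk(k) * ld;
    nlog2pi += vk(k) * nk(k) * log2pi;
  }

  arma::vec beta;
  if (profile_beta) {
    const bool ok = arma::solve(beta, A, bvec, arma::solve_opts::no_approx);
    if (!ok) stop("singular weighted information matrix: "
                  "a fixed-effect column has no support");
  } else {
    beta = beta_in;
  }

  const double quad = Syy - 2.0 * arma::dot(beta, bvec) +
    arma::as_scalar(beta.t() * A * beta);
  const double loglik = -0.5 * (nlog2pi + logdet + quad);

  double ldA, ldA_sign;
  arma::log_det(ldA, ldA_sign, A);

  List out = List::create(
    Named("loglik") = loglik,
    Named("beta") = beta,
    Named("A") = A,
    Named("bread") = bread,
    Named("logdet_vinfo") = (ldA_sign > 0.0) ? ldA : NA_REAL);

  if (want_blups || want_scores) {
    arma::mat blups(K, 2), scores(K, p);
    for (int k = 0; k < K; ++k) {
      const double g11 = G_all(0, k), g21 = G_all(1, k);
      const double g12 = G_all(2, k), g22 = G_all(3, k);
      uy(0) = uy1(k) * inv_se;
      uy(1) = uy0(k) * inv_se;
      Ux.col(0) = Xwt.col(k) * inv_se;
      Ux.col(1) = Xwc.col(k) * inv_se;
      if (want_blups) {
        const arma::vec ur = uy - Ux.t() * beta;  // Z'D^{-1} r
        blups(k, 0) = g11 * ur(0) + g12 * ur(1);
        blups(k, 1) = g21 * ur(0) + g22 * ur(1);
      }
      if (want_scores) {
        const double guy0 = g11 * uy(0) + g12 * uy(1);
        const double guy1 = g21 * uy(0) + g22 * uy(1);
        XtViy = XtWy.col(k) * inv_se - Ux.col(0) * guy0 - Ux.col(1) * guy1;
        const arma::vec gu0 = g11 * Ux.col(0) + g12 * Ux.col(1);
        const arma::vec gu1 = g21 * Ux.col(0) + g22 * Ux.col(1);
        XtViX = XtWX.slice(k) * inv_se;
        XtViX -= Ux.col(0) * gu0.t() + Ux.col(1) * gu1.t();
        scores.row(k) = (XtViy - XtViX * beta).t();
      }
    }
    if (want_blups) out["blups"] = blups;
    if (want_scores) out["scores"] = scores;
  }
  return out;
}
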