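#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// scaled squared-distance matrix: S_pq = sum_j (x_pj - x'_qj)^2 / l_j^2
static arma::mat scaled_sqdist(const arma::mat& X1, const arma::mat& X2,
                               const arma::vec& ls) {
  arma::mat A = X1.each_row() / ls.t();
  arma::mat B = X2.each_row() / ls.t();
  arma::vec a2 = arma::sum(arma::square(A), 1);
  arma::vec b2 = arma::sum(arma::square(B), 1);
  arma::mat S = -2.0 * (A * B.t());
  S.each_col() += a2;
  S.each_row() += b2.t();
  S.clamp(0.0, arma::datum::inf);
  return S;
}

// Squared-exponential (ARD) covariance between row sets:
// k(x, x') = sf2 * exp(-1/2 sum_j (x_j - x'_j)^2 / l_j^2)
// [[Rcpp::export]]
arma::mat se_cross_cov(const arma::mat& X1, const arma::mat& X2,
                       const arma::vec& ls, double sf2) {
  return sf2 * arma::exp(-0.5 * scaled_sqdist(X1, X2, ls));
}

static bool chol_with_jitter(arma::mat& L, const arma::mat& K, double scale,
                             double& jitter_used) {
  // jitter ladder: 0, 1e-10, 1e-8, 1e-6 (relative to the diagonal scale)
  const double ladder[4] = {0.0, 1e-10, 1e-8, 1e-6};
  for (int k = 0; k < 4; k++) {
    arma::mat Kj = K;
    Kj.diag() += ladder[k] * scale;
    if (arma::chol(L, Kj, "lower")) {
      // a successful factorization with a near-zero pivot is numerically
      // worthless (cond(K) ~ (max/min)^2): climb the ladder instead
      if (L.diag().min() <= 1e-6 * L.diag().max() && k < 3) continue;
      jitter_used = ladder[k] * scale;
      return true;
    }
  }
  return false;
}

// Profiled negative log marginal likelihood of a GP with trend matrix H
// (GLS-profiled beta) and its gradient in log-hyperparameter space.
// theta = (log l_1..log l_d, log sf2, log nugget).
// [[Rcpp::export]]
List gp_nll_grad(const arma::mat& X, const arma::vec& y, const arma::mat& H,
                 const arma::vec& theta, bool want_grad) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  arma::vec ls = arma::exp(theta.subvec(0, d - 1));
  const double sf2 = std::exp(theta(d));
  const double nug = std::exp(theta(d + 1));

  arma::mat Kse = se_cross_cov(X, X, ls, sf2);
  Kse = 0.5 * (Kse + Kse.t());   // exact symmetry (GEMM rounding)
  arma::mat K = Kse;
  K.diag() += nug;

  arma::mat L;
  double jit = 0.0;
  if (!chol_with_jitter(L, K, sf2 + nug, jit))
    return List::create(_["ok"] = false);

  arma::mat Li = arma::inv(arma::trimatl(L));
  arma::mat Kinv = Li.t() * Li;
  arma::mat KiH = Kinv * H;
  arma::mat A = H.t() * KiH;           // p x p
  arma::vec Kiy = Kinv * y;
  arma::vec beta = arma::solve(A, H.t() * Kiy, arma::solve_opts::likely_sympd);
  arma::vec r = y - H * beta;
  arma::vec alpha = Kinv * r;

  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  double nll = 0.5 * arma::dot(r, alpha) + 0.5 * logdet +
               0.5 * n * std::log(2.0 * M_PI);

  if (!want_grad)
    return List::create(_["ok"] = true, _["nll"] = nll, _["beta"] = beta,
                        _["jitter"] = jit);

  // dL/dtheta_k = 1/2 tr((alpha alpha' - Kinv) dK/dtheta_k); envelope in beta.
  // For log l_j: dK/dlog l_j = Kse % D_j with D_j the scaled squared distance
  // in dimension j alone; accu(M % D_j) expands to quadratic forms in the
  // scaled column, giving an O(n^2 d) batched computation.
  arma::mat M = (alpha * alpha.t() - Kinv) % Kse;  // symmetric
  arma::vec grad(d + 2, arma::fill::zeros);
  arma::mat As = X.each_row() / ls.t();            // n x d scaled columns
  arma::vec rs = arma::sum(M, 1);                  // row sums of M
  arma::mat MA = M * As;                           // n x d
  for (arma::uword j = 0; j < d; j++) {
    double q = arma::dot(arma::square(As.col(j)), rs) -
               arma::dot(As.col(j), MA.col(j));
    grad(j) = -0.5 * 2.0 * q;                      // accu(M % D_j) = 2q
  }
  double trW = arma::dot(alpha, alpha) - arma::trace(Kinv);
  grad(d) = -0.5 * arma::accu(M);                  // dK/dlog sf2 = Kse
  grad(d + 1) = -0.5 * nug * trW;                  // dK/dlog nug = nug I
  return List::create(_["ok"] = true, _["nll"] = nll, _["grad"] = grad,
                      _["beta"] = beta, _["jitter"] = jit);
}

// Universal-kriging posterior at Xnew given training data and
// hyperparameters. Returns mean and latent variance (no nugget), including
// the trend estimation correction term.
// [[Rcpp::export]]
List gp_posterior(const arma::mat& X, const arma::vec& y, const arma::mat& H,
                  const arma::mat& Xnew, const arma::mat& Hnew,
                  const arma::vec& ls, double sf2, double nug, double jitter) {
  arma::mat K = se_cross_cov(X, X, ls, sf2);
  K = 0.5 * (K + K.t());
  K.diag() += nug + jitter;
  arma::mat L;
  if (!arma::chol(L, K, "lower")) {
    double j2 = jitter;
    if (!chol_with_jitter(L, K, sf2 + nug, j2))
      stop("covariance factorization failed");
  }
  arma::mat Li = arma::inv(arma::trimatl(L));
  arma::mat Kinv = Li.t() * Li;
  arma::mat KiH = Kinv * H;
  arma::mat A = H.t() * KiH;
  arma::vec beta = arma::solve(A, H.t() * (Kinv * y),
                               arma::solve_opts::likely_sympd);
  arma::vec alpha = Kinv * (y - H * beta);

  arma::mat Ks = se_cross_cov(Xnew, X, ls, sf2);   // m x n
  arma::vec mean = Hnew * beta + Ks * alpha;

  arma::mat V = Li * Ks.t();                        // n x m
  arma::mat U = Hnew.t() - KiH.t() * Ks.t();        // p x m
  arma::mat Ainv = arma::inv_sympd(arma::symmatu(A));
  arma::mat AiU = Ainv * U;                         // p x m
  arma::vec var(Xnew.n_rows);
  for (arma::uword i = 0; i < Xnew.n_rows; i++) {
    double v = sf2 - arma::dot(V.col(i), V.col(i)) +
               arma::dot(U.col(i), AiU.col(i));
    var(i) = v > 0 ? v : 0.0;
  }
  return List::create(_["mean"] = mean, _["var"] = var, _["beta"] = beta);
}
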