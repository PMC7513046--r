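// Simultaneous orthogonal matching pursuit over a shared atom support,
// plus the batched low-pass patch fusion loop (SOMP -> Max-L1 -> rebuild).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Greedy joint sparse coding of a signal pair on a common support.
// Atom choice maximises |phi' r_a| + |phi' r_b|; coefficients are
// per-signal least squares on the shared support; stops when both
// residual norms drop to eps or the support reaches max_atoms.
static void somp_pair(const mat& phi, const vec& ya, const vec& yb,
                      double eps, int max_atoms,
                      std::vector<uword>& S, vec& ca, vec& cb,
                      double& res_a, double& res_b) {
  const uword cap = std::min<uword>(std::max(max_atoms, 0),
                                    std::min(phi.n_rows, phi.n_cols));
  S.clear();
  vec ra = ya, rb = yb;
  ca.reset(); cb.reset();
  while ((norm(ra, 2) > eps || norm(rb, 2) > eps) && S.size() < cap) {
    vec score = abs(phi.t() * ra) + abs(phi.t() * rb);
    for (uword s : S) score(s) = -1.0;
    uword j = score.index_max();
    if (score(j) < 1e-13) break;  // residuals orthogonal to the dictionary
    S.push_back(j);
    uvec Su = conv_to<uvec>::from(S);
    mat Ps = phi.cols(Su);
    ca = solve(Ps, ya);
    cb = solve(Ps, yb);
    ra = ya - Ps * ca;
    rb = yb - Ps * cb;
  }
  res_a = norm(ra, 2);
  res_b = norm(rb, 2);
}

// [[Rcpp::export]]
Rcpp::List somp_encode_cpp(const arma::mat& phi,
                           const arma::vec& va, const arma::vec& vb,
                           double eps, int max_atoms) {
  std::vector<uword> S;
  vec ca, cb;
  double res_a, res_b;
  somp_pair(phi, va, vb, eps, max_atoms, S, ca, cb, res_a, res_b);

  vec full_a(phi.n_cols, fill::zeros), full_b(phi.n_cols, fill::zeros);
  Rcpp::IntegerVector support(S.size());
  for (size_t i = 0; i < S.size(); ++i) {
    support[i] = (int)S[i] + 1;  // 1-based for R
    full_a(S[i]) = ca(i);
    full_b(S[i]) = cb(i);
  }
  return Rcpp::List::create(
    Rcpp::Named("support") = support,
    Rcpp::Named("coef_a") = full_a,
    Rcpp::Named("coef_b") = full_b,
    Rcpp::Named("residual_a") = res_a,
    Rcpp::Named("residual_b") = res_b);
}

// Fuse every patch pair: SOMP joint code, Max-L1 winner (ties -> B),
// rebuild winner's code plus winner's stored mean.
// Returns the fused patch matrix and the per-patch winner (0 = A, 1 = B).
// [[Rcpp::export]]
Rcpp::List fuse_lowpass_core_cpp(const arma::mat& phi,
                                 const arma::mat& va, const arma::mat& vb,
                                 const arma::vec& mean_a, const arma::vec& mean_b,
                                 double eps, int max_atoms) {
  const uword n = va.n_rows, T = va.n_cols;
  mat fused(n, T);
  Rcpp::IntegerVector winner(T);
  std::vector<uword> S;
  vec ca, cb;
  double res_a, res_b;

  for (uword t = 0; t < T; ++t) {
    somp_pair(phi, va.col(t), vb.col(t), eps, max_atoms, S, ca, cb, res_a, res_b);
    double l1a = (ca.n_elem > 0) ? accu(abs(ca)) : 0.0;
    double l1b = (cb.n_elem > 0) ? accu(abs(cb)) : 0.0;
    bool a_wins = l1a > l1b;  // tie goes to B
    winner[t] = a_wins ? 0 : 1;
    vec patch(n, fill::zeros);
    if (!S.empty()) {
      uvec Su = conv_to<uvec>::from(S);
      patch = phi.cols(Su) * (a_wins ? ca : cb);
    }
    patch += (a_wins ? mean_a(t) : mean_b(t));
    fused.col(t) = patch;
  }
  return Rcpp::List::create(
    Rcpp::Named("fused") = fused,
    Rcpp::Named("winner") = winner);
}
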