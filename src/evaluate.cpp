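#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// One evaluation pass of the weight estimator over all K samples.
//
// For sample k with Jacobian J (m x n), current weights w and projection
// ratio gamma:
//   M      = J W^-1 J'                  (must be well-conditioned)
//   task_k = W^-1 J' M^-1 xdot_k        (minimum-cost task component)
//   u_k    = J' M^-1 xdot_k             (auxiliary variable of the update)
//   v_k    = gamma (qdot_k - W^-1 J' M^-1 J qdot_k) = gamma N qdot_k
//   r_k    = || qdot_k - task_k - v_k ||
//
// On a near-singular M the 1-based offending sample index is returned in
// `singular` and the caller raises a classed R error.
//
// [[Rcpp::export]]
Rcpp::List ikw_eval_cpp(const arma::mat& Qd, const arma::mat& Xd,
                        const arma::cube& Jarr, const arma::vec& w,
                        double gamma, double rcond_tol) {
  const uword n = Qd.n_rows, K = Qd.n_cols, m = Xd.n_rows;
  mat V(n, K, fill::zeros), U(n, K, fill::zeros), task(n, K, fill::zeros);
  vec resid(K, fill::zeros);
  mat rhs(m, 2);

  for (uword k = 0; k < K; ++k) {
    const mat& J = Jarr.slice(k);
    mat WiJt = J.t();
    WiJt.each_col() /= w;               // W^-1 J'
    mat M = J * WiJt;                   // J W^-1 J'
    double rc = rcond(M);
    if (!std::isfinite(rc) || rc < rcond_tol)
      return Rcpp::List::create(Rcpp::Named("singular") = (int)(k + 1),
                                Rcpp::Named("rcond") = rc);
    vec qk = Qd.col(k);
    rhs.col(0) = Xd.col(k);
    rhs.col(1) = J * qk;
    mat S = solve(M, rhs, solve_opts::likely_sympd);
    mat T = WiJt * S;                   // [task, J# J qdot]
    task.col(k) = T.col(0);
    U.col(k) = J.t() * S.col(0);
    vec vk = gamma * (qk - T.col(1));
    V.col(k) = vk;
    resid(k) = norm(qk - T.col(0) - vk);
  }
  return Rcpp::List::create(
    Rcpp::Named("e") = mean(resid),
    Rcpp::Named("V") = V,
    Rcpp::Named("U") = U,
    Rcpp::Named("task") = task,
    Rcpp::Named("resid") = resid);
}
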