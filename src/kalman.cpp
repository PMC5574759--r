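// Kalman filter/smoother for the stochastic response function
//   state  a_t = (mu_t, delta_t, alpha_t)
//   mu_t    = mu_{t-1} + delta_{t-1}
//   delta_t = delta_{t-1} + zeta_t,   zeta ~ N(0, s2_zeta)
//   alpha_t = alpha_{t-1} + eta_t,    eta  ~ N(0, s2_eta)
//   y_t     = mu_t + x_t * alpha_t + eps_t,  eps ~ N(0, s2_eps)
// Missing y_t: prediction only, no update.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List kalman_run(const arma::vec& y, const arma::vec& x,
                const double s2_eps, const double s2_zeta,
                const double s2_eta, const arma::vec& a0,
                const arma::mat& P0, const int burn,
                const bool smooth) {
  const int n = y.n_elem;
  arma::mat T(3, 3, arma::fill::eye);
  T(0, 1) = 1.0;
  arma::mat Q(3, 3, arma::fill::zeros);
  Q(1, 1) = s2_zeta;
  Q(2, 2) = s2_eta;

  arma::mat a_pred(3, n), a_filt(3, n);
  arma::cube P_pred(3, 3, n), P_filt(3, 3, n);
  arma::vec a = a0;
  arma::mat P = P0;
  double loglik = 0.0;
  int seen = 0;
  const double l2pi = std::log(2.0 * M_PI);

  for (int t = 0; t < n; ++t) {
    if (t > 0) {
      a = T * a;
      P = T * P * T.t() + Q;
    }
    a_pred.col(t) = a;
    P_pred.slice(t) = P;

    if (arma::is_finite(y(t))) {
      arma::rowvec Z = {1.0, 0.0, x(t)};
      double F = arma::as_scalar(Z * P * Z.t()) + s2_eps;
      double v = y(t) - arma::as_scalar(Z * a);
      arma::vec K = P * Z.t() / F;
      a = a + K * v;
      P = P - K * Z * P;
      P = 0.5 * (P + P.t());
      ++seen;
      if (seen > burn && F > 0.0)
        loglik += -0.5 * (l2pi + std::log(F) + v * v / F);
    }
    a_filt.col(t) = a;
    P_filt.slice(t) = P;
  }

  List out = List::create(
    Named("loglik") = loglik,
    Named("a_filt") = a_filt,
    Named("P_filt_diag") = R_NilValue,
    Named("a_smooth") = R_NilValue,
    Named("P_smooth_diag") = R_NilValue);

  arma::mat pf_diag(3, n);
  for (int t = 0; t < n; ++t) pf_diag.col(t) = P_filt.slice(t).diag();
  out["P_filt_diag"] = pf_diag;

  if (smooth) {
    arma::mat a_sm(3, n);
    arma::cube P_sm(3, 3, n);
    a_sm.col(n - 1) = a_filt.col(n - 1);
    P_sm.slice(n - 1) = P_filt.slice(n - 1);
    for (int t = n - 2; t >= 0; --t) {
      arma::mat Pp = P_pred.slice(t + 1);
      arma::mat J = P_filt.slice(t) * T.t() * arma::pinv(Pp);
      a_sm.col(t) = a_filt.col(t) +
        J * (a_sm.col(t + 1) - a_pred.col(t + 1));
      P_sm.slice(t) = P_filt.slice(t) +
        J * (P_sm.slice(t + 1) - Pp) * J.t();
    }
    arma::mat ps_diag(3, n);
    for (int t = 0; t < n; ++t) ps_diag.col(t) = P_sm.slice(t).diag();
    out["a_smooth"] = a_sm;
    out["P_smooth_diag"] = ps_diag;
  }
  return out;
}
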