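// Missing-data Kalman filter and Rauch-Tung-Striebel smoother for the
// random-walk-transition Gaussian state-space model
//
//   x_t = x_{t-1} + cc_t + w_t,  w_t ~ N(0, diag(Qd))
//   y_t = Z_t x_t + v_t,         v_t ~ N(0, diag(Rd))
//
// with x_0 ~ N(x0, diag(V0d)).  cc_t is the covariate contribution C c_t,
// precomputed by the caller.  Missing observation components (NaN) are
// marginalised out of each update; a fully missing time step is a pure
// prediction step.  Z may be a single slice (time-invariant) or one slice
// per time step.
//
// The smoother additionally returns the lag-one smoothed covariances
// cov(x_t, x_{t-1} | y_{1:T}) and the smoothed moments of x_0, which are
// the sufficient statistics the EM M-steps need.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Symmetric-solve helper: X = A^{-1} B for symmetric PSD A, with a
// pseudo-inverse fallback so exactly degenerate (zero-variance) predictions
// smooth correctly in the Q = 0, V0 = 0 limit.
static mat psd_solve(const mat& A, const mat& B) {
  mat As = symmatu(A), L;
  if (chol(L, As, "lower"))
    return solve(trimatu(L.t()), solve(trimatl(L), B));
  return pinv(As) * B;  // exactly degenerate (zero-variance) direction
}

// [[Rcpp::export(name = ".kalman_cpp")]]
Rcpp::List kalman_cpp(const arma::mat& y,     // p x T, NaN = missing
                      const arma::cube& Z,    // p x m x {1,T}
                      const arma::vec& Qd,    // m
                      const arma::vec& Rd,    // p
                      const arma::mat& cc,    // m x T
                      const arma::vec& x0,    // m
                      const arma::vec& V0d,   // m
                      const bool smooth) {
  const uword p = y.n_rows, T = y.n_cols, m = Z.n_cols;
  const bool tvZ = (Z.n_slices > 1);
  const double ln2pi = std::log(2.0 * arma::datum::pi);

  mat xp(m, T), xf(m, T);
  cube Pp(m, m, T), Pf(m, m, T);
  double loglik = 0.0;

  vec xpred = x0 + cc.col(0);
  mat Ppred = diagmat(V0d) + diagmat(Qd);

  for (uword t = 0; t < T; ++t) {
    xp.col(t) = xpred;
    Pp.slice(t) = Ppred;

    uvec obs = find_finite(y.col(t));
    if (obs.n_elem == 0) {
      xf.col(t) = xpred;
      Pf.slice(t) = Ppred;
    } else {
      const mat& Zt = tvZ ? Z.slice(t) : Z.slice(0);
      mat Zo = Zt.rows(obs);
      vec v = y.submat(obs, uvec{t}) - Zo * xpred;
      mat F = symmatu(Zo * Ppred * Zo.t()) + diagmat(Rd.elem(obs));
      mat L;
      if (!chol(L, F, "lower"))
        Rcpp::stop("innovation covariance numerically singular at time step %d",
                   (int)(t + 1));
      vec alpha = solve(trimatl(L), v);
      double logdet = 2.0 * accu(log(L.diag()));
      loglik += -0.5 * (obs.n_elem * ln2pi + logdet + dot(alpha, alpha));
      // K = Ppred Zo' F^{-1}
      mat K = solve(trimatl(L), Zo * Ppred);          // L^{-1} Zo P
      K = solve(trimatu(L.t()), K).t();               // (F^{-1} Zo P)' = P Zo' F^{-1}
      xf.col(t) = xpred + K * v;
      mat Pupd = Ppred - K * Zo * Ppred;
      Pf.slice(t) = symmatu(0.5 * (Pupd + Pupd.t()));
    }
    if (t + 1 < T) {
      xpred = xf.col(t) + cc.col(t + 1);
      Ppred = Pf.slice(t) + diagmat(Qd);
    }
  }

  if (!smooth)
    return Rcpp::List::create(Rcpp::Named("loglik") = loglik,
                              Rcpp::Named("xp") = xp, Rcpp::Named("Pp") = Pp,
                              Rcpp::Named("xf") = xf, Rcpp::Named("Pf") = Pf);

  mat xs(m, T);
  cube Ps(m, m, T), Pcs(m, m, T, fill::zeros);
  xs.col(T - 1) = xf.col(T - 1);
  Ps.slice(T - 1) = Pf.slice(T - 1);

  cube J(m, m, T);  // J.slice(t) maps smoothing correction from t+1 back to t
  for (uword t = T - 1; t-- > 0;) {
    mat Jt = psd_solve(Pp.slice(t + 1), Pf.slice(t)).t();  // Pf_t Pp_{t+1}^{-1}
    J.slice(t) = Jt;
    xs.col(t) = xf.col(t) + Jt * (xs.col(t + 1) - xp.col(t + 1));
    mat Pst = Pf.slice(t) + Jt * (Ps.slice(t + 1) - Pp.slice(t + 1)) * Jt.t();
    Ps.slice(t) = symmatu(0.5 * (Pst + Pst.t()));
    Pcs.slice(t + 1) = Ps.slice(t + 1) * Jt.t();  // cov(x_{t+1}, x_t | y)
  }

  // smoothed moments of x_0 (prior N(x0, V0)); J0 = V0 Pp_1^{-1}
  mat J0 = psd_solve(Pp.slice(0), diagmat(V0d)).t();
  vec xs0 = x0 + J0 * (xs.col(0) - xp.col(0));
  mat Ps0 = diagmat(V0d) + J0 * (Ps.slice(0) - Pp.slice(0)) * J0.t();
  Pcs.slice(0) = Ps.slice(0) * J0.t();  // cov(x_1, x_0 | y)

  return Rcpp::List::create(
      Rcpp::Named("loglik") = loglik, Rcpp::Named("xp") = xp,
      Rcpp::Named("Pp") = Pp, Rcpp::Named("xf") = xf, Rcpp::Named("Pf") = Pf,
      Rcpp::Named("xs") = xs, Rcpp::Named("Ps") = Ps,
      Rcpp::Named("Pcs") = Pcs, Rcpp::Named("xs0") = xs0,
      Rcpp::Named("Ps0") = symmatu(0.5 * (Ps0 + Ps0.t())));
}
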