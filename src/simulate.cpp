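// Euler-Maruyama integrator for the linear Langevin field dynamics
//   eta_{n+1} = eta_n + dt * Lambda eta_n + sqrt(dt) * B z_n ,  B B' = Gamma.
// Uses R's RNG (norm_rand) so trajectories are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::NumericMatrix em_integrate(const arma::mat& step_matrix,
                                 const arma::mat& noise_factor,
                                 const arma::vec& eta0,
                                 const int n_steps,
                                 const int burn_in,
                                 const int save_stride,
                                 const double sqrt_dt) {
  const int n = eta0.n_elem;
  const int n_keep = n_steps - burn_in;
  const int n_saved = n_keep / save_stride;
  Rcpp::NumericMatrix out(n_saved, n);
  arma::vec eta = eta0, z(n);

  Rcpp::RNGScope scope;
  int saved = 0;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) z[i] = norm_rand();
    eta = step_matrix * eta + sqrt_dt * (noise_factor * z);
    if (!eta.is_finite())
      Rcpp::stop("trajectory diverged at step %d: reduce dt", s);
    if (s > burn_in && (s - burn_in) % save_stride == 0) {
      for (int i = 0; i < n; ++i) out(saved, i) = eta[i];
      ++saved;
      if (saved == n_saved) break;
    }
  }
  return out;
}

// Per-step increments of the Stratonovich entropy-production sum
//   inc_n = 2 * (eta_{n+1} - eta_n)' Ginv Lambda (eta_{n+1} + eta_n) / 2 .
// [[Rcpp::export]]
arma::vec strat_increments(const arma::mat& fields,
                           const arma::mat& ginv_drift) {
  const int T = fields.n_rows;
  if (T < 2) Rcpp::stop("need at least two saved configurations");
  arma::vec inc(T - 1);
  for (int t = 0; t < T - 1; ++t) {
    arma::rowvec d = fields.row(t + 1) - fields.row(t);
    arma::rowvec m = 0.5 * (fields.row(t + 1) + fields.row(t));
    inc[t] = 2.0 * arma::dot(d, m * ginv_drift.t());
  }
  return inc;
}

// Backward-minus-forward Onsager-Machlup action, accumulated per step so the
// quadratic terms cancel at per-step scale instead of between two large
// global sums.
// [[Rcpp::export]]
double om_action_difference(const arma::mat& fields,
                            const arma::mat& drift,
                            const arma::mat& ginv,
                            const double dt) {
  const int T = fields.n_rows;
  if (T < 2) Rcpp::stop("need at least two saved configurations");
  double acc = 0.0;
  for (int t = 0; t < T - 1; ++t) {
    arma::vec d = (fields.row(t + 1) - fields.row(t)).t() / dt;
    arma::vec m = 0.5 * (fields.row(t + 1) + fields.row(t)).t();
    arma::vec lm = drift * m;
    arma::vec rf = d - lm, rb = -d - lm;
    acc += 0.5 * dt * (arma::as_scalar(rb.t() * ginv * rb) -
                       arma::as_scalar(rf.t() * ginv * rf));
  }
  return acc;
}

// Discrete Onsager-Machlup action
//   (dt/2) * sum_n r_n' Ginv r_n,  r_n = (eta_{n+1}-eta_n)/dt -+ Lambda etabar_n
// sign = -1 for the forward residual, +1 for the backward one.
// [[Rcpp::export]]
double om_action(const arma::mat& fields,
                 const arma::mat& drift,
                 const arma::mat& ginv,
                 const double dt,
                 const int sign) {
  const int T = fields.n_rows;
  if (T < 2) Rcpp::stop("need at least two saved configurations");
  double acc = 0.0;
  for (int t = 0; t < T - 1; ++t) {
    arma::vec d = (fields.row(t + 1) - fields.row(t)).t() / dt;
    arma::vec m = 0.5 * (fields.row(t + 1) + fields.row(t)).t();
    arma::vec r = (sign < 0) ? arma::vec(d - drift * m)
                             : arma::vec(-d - drift * m);
    acc += arma::as_scalar(r.t() * ginv * r);
  }
  return 0.5 * dt * acc;
}
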