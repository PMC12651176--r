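make_traj <- function(fields, dt, drift, noise_cov) {
  structure(list(times = dt * seq_len(nrow(fields)), fields = fields,
                 dt = dt, save_stride = 1L, seed = 0L,
                 model_fingerprint =
                   amariepr:::model_fingerprint(drift, noise_cov)),
            class = "amari_trajectory")
}

test_that("path action reproduces the hand-computed discrete sum", {
  # 1-site model, Lambda = -1, Gamma = 1, dt = 1, eta = [0, 1]:
  # forward residual 1 - (-1/2) = 3/2, action = (1/2)(3/2)^2 = 9/8
  drift <- matrix(-1, 1, 1); G <- matrix(1, 1, 1)
  tr <- make_traj(matrix(c(0, 1), 2, 1), dt = 1, drift, G)
  expect_equal(path_action(tr, drift, G, "forward"), 9 / 8)
  # backward residual -1 + 1/2 = -1/2, action = 1/8
  expect_equal(path_action(tr, drift, G, "backward"), 1 / 8)
})

test_that("backward action equals forward action on the reversed trajectory", {
  set.seed(9)
  drift <- random_stable_drift(4)
  G <- random_spd(4)
  tr <- make_traj(matrix(rnorm(200), 50, 4), dt = 0.05, drift, G)
  expect_equal(path_action(tr, drift, G, "backward"),
               path_action(time_reverse(tr), drift, G, "forward"),
               tolerance = 1e-12)
  expect_gte(path_action(tr, drift, G, "forward"), 0)
})

test_that("action of the exact deterministic solution vanishes with dt", {
  drift <- rotation_drift(1, 1)
  G <- diag(2)
  horizon <- 1
  act_at <- function(dt) {
    ts <- seq(0, horizon, by = dt)
    # exact flow of the rotation drift: e^{-at} (cos bt, sin bt) from (1, 0)
    fields <- cbind(exp(-ts) * cos(ts), exp(-ts) * sin(ts))
    path_action(make_traj(fields, dt, drift, G), drift, G, "forward")
  }
  a1 <- act_at(0.01)
  expect_lt(a1, 0.01)
  # the midpoint residual of the exact flow is O(dt^2), so the action decays
  # much faster than the O(dt) bound
  expect_lt(act_at(0.005) / a1, 0.3)
})

test_that("Stratonovich sum and action difference are the same functional", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(2:6, 1)
    drift <- random_stable_drift(n)
    G <- random_spd(n)
    tr <- simulate_field(drift, G, simulation_config(0.005, 1e5,
                                                     burn_in = 500, seed = i))
    est <- lebowitz_spohn_estimate(tr, drift, G)
    expect_lte(est$om_consistency_gap,
               1e-9 * (1 + abs(est$sigma_hat * est$horizon)))
  }
})

test_that("path estimator agrees with the analytic rate", {
  # equilibrium: consistent with zero
  m <- ring_model(8, "gaussian")
  nz <- white_noise_for(m)
  tr <- simulate_field(m, nz, simulation_config(0.005, 1e5, burn_in = 1000,
                                                seed = 21))
  est <- lebowitz_spohn_estimate(tr, m$drift_matrix, nz$covariance)
  expect_lt(abs(est$sigma_hat), 3 * est$standard_error)
  # rotation system: sigma = 2 within 3 SE
  rot <- rotation_drift(1, 1)
  tr2 <- simulate_field(rot, diag(2), simulation_config(1e-3, 5e5,
                                                        burn_in = 2000,
                                                        seed = 22))
  est2 <- lebowitz_spohn_estimate(tr2, rot, diag(2))
  expect_lt(abs(est2$sigma_hat - 2), 3 * est2$standard_error)
  # running estimate converges toward the final value
  tail_val <- utils::tail(est2$running_sigma$sigma, 1)
  expect_equal(tail_val, est2$sigma_hat, tolerance = 1e-6)
  # model fingerprint mismatch is refused
  expect_error(lebowitz_spohn_estimate(tr2, rot, 2 * diag(2)),
               "not generated")
})

test_that("reservoir Monte-Carlo rate matches the trace formula", {
  # equilibrium: current vanishes, estimate consistent with zero
  m <- ring_model(8, "gaussian")
  nz <- white_noise_for(m)
  st <- solve_lyapunov(m$drift_matrix, nz$covariance)
  mc <- reservoir_entropy_rate_mc(m$drift_matrix, nz$covariance, st,
                                  n_samples = 2e4, seed = 1)
  expect_lt(abs(mc$s_dot_res), 3 * mc$standard_error + 1e-10)
  # rotation system
  rot <- rotation_drift(1, 1)
  st2 <- solve_lyapunov(rot, diag(2))
  mc2 <- reservoir_entropy_rate_mc(rot, diag(2), st2, n_samples = 1e5,
                                   seed = 2)
  expect_lt(abs(mc2$s_dot_res - 2), 3 * mc2$standard_error)
  # split-half consistency of the i.i.d. sampler
  mc_a <- reservoir_entropy_rate_mc(rot, diag(2), st2, n_samples = 5e4,
                                    seed = 3)
  mc_b <- reservoir_entropy_rate_mc(rot, diag(2), st2, n_samples = 5e4,
                                    seed = 4)
  comb <- sqrt(mc_a$standard_error^2 + mc_b$standard_error^2)
  expect_lt(abs(mc_a$s_dot_res - mc_b$s_dot_res), 3 * comb)
})

test_that("Shannon entropy rate decomposition is exact at stationarity", {
  # equilibrium: everything vanishes
  m <- ring_model(8, "gaussian")
  nz <- white_noise_for(m)
  st <- solve_lyapunov(m$drift_matrix, nz$covariance)
  dec <- shannon_entropy_rate_decomposition(m$drift_matrix, nz$covariance, st)
  expect_lt(abs(dec$s_dot_tot), 1e-10)
  expect_lt(abs(dec$s_dot_res), 1e-10)
  expect_lt(abs(dec$s_dot_sys), 1e-10)
  # rotation system: total = reservoir = 2, system rate zero
  rot <- rotation_drift(1, 1)
  st2 <- solve_lyapunov(rot, diag(2))
  dec2 <- shannon_entropy_rate_decomposition(rot, diag(2), st2)
  expect_equal(dec2$s_dot_tot, 2, tolerance = 1e-10)
  expect_equal(dec2$s_dot_res, 2, tolerance = 1e-10)
  expect_lt(abs(dec2$s_dot_sys), 1e-10)
  # random stable systems: total rate nonnegative, equals the trace formula
  set.seed(17)
  for (i in 1:6) {
    n <- sample(2:10, 1)
    drift <- random_stable_drift(n)
    G <- random_spd(n)
    sti <- solve_lyapunov(drift, G)
    di <- shannon_entropy_rate_decomposition(drift, G, sti)
    expect_gte(di$s_dot_tot, -1e-12)
    s_trace <- entropy_production_trace(drift, G, sti)
    expect_equal(di$s_dot_tot, s_trace, tolerance = 1e-10)
    expect_equal(di$s_dot_res, s_trace, tolerance = 1e-10)
  }
})

test_that("equal-time noise-field correlation carries the Stratonovich half", {
  # <xi eta> at equal times equals Gamma / 2: measured through
  # <etadot eta'> = Lambda C + Gamma / 2 on a simulated run
  rot <- rotation_drift(1, 1)
  G <- diag(2)
  st <- solve_lyapunov(rot, G)
  tr <- simulate_field(rot, G, simulation_config(1e-3, 4e5, burn_in = 2000,
                                                 seed = 33))
  F <- tr$fields
  Tn <- nrow(F)
  D <- (F[-1, ] - F[-Tn, ]) / tr$dt
  M <- (F[-1, ] + F[-Tn, ]) / 2
  emp <- crossprod(D, M) / (Tn - 1)
  theory <- rot %*% st$covariance + G / 2
  # noise-dominated estimator: generous 3-SE-scale tolerance
  se_scale <- sqrt(1 / (tr$dt * Tn)) * max(abs(G))
  expect_lt(max(abs(emp - theory)), 3 * se_scale)
})
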