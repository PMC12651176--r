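test_that("Fourier eigenvalues coincide with the circulant drift spectrum", {
  # zero kernel: every mode relaxes at the leak rate
  g <- discrete_grid(8)
  m0 <- build_model(g, 2, sigmoid(2, 0.5), kernel_spec("zero"))
  sp0 <- fourier_eigenvalues(m0)
  expect_equal(sp0$modes$lambda_k, rep(complex(real = -0.5), 8))
  # even kernel: real transform, real eigenvalues
  m <- ring_model(16, "gaussian")
  sp <- fourier_eigenvalues(m)
  expect_lt(max(abs(Im(sp$modes$w_k))), 1e-12)
  expect_lt(max(abs(Im(sp$modes$lambda_k))), 1e-12)
  # multiset equality with the dense eigendecomposition, asymmetric case
  ma <- ring_model(16, "shifted_gaussian", shift = 0.7)
  spa <- fourier_eigenvalues(ma)
  ev_dense <- eigen(ma$drift_matrix, only.values = TRUE)$values
  srt <- function(z) z[order(Re(z), Im(z))]
  expect_equal(srt(spa$modes$lambda_k), srt(ev_dense), tolerance = 1e-10)
  # mode bookkeeping: m runs over [-N/2, N/2), k = 2 pi m / L
  expect_equal(spa$modes$m, -8:7)
  expect_equal(spa$modes$k, 2 * pi * (-8:7) / ma$grid$length)
  # non-circulant kernels are refused
  W <- matrix(0.1, 4, 4); W[1, 2] <- 0.4
  g4 <- discrete_grid(4)
  mnc <- list(grid = g4, tau = 1, gain_at_fp = 0.5, kernel_matrix = W,
              drift_matrix = build_linear_operator(g4, 1, W, 0.5))
  class(mnc) <- "amari_model"
  expect_error(fourier_eigenvalues(mnc), "translational invariance")
})

test_that("per-mode entropy production follows -Im^2/Re", {
  expect_equal(mode_epr(-1 + 0i), 0)
  expect_equal(mode_epr(-1 + 1i), 1)
  expect_equal(mode_epr(-2 + 3i), 4.5)
  expect_equal(mode_epr(-2 - 3i), 4.5)     # conjugate pair symmetry
  expect_error(mode_epr(1 + 1i), "negative")
  # nonnegative, zero iff real
  set.seed(3)
  lam <- complex(real = -runif(50, 0.1, 3), imaginary = rnorm(50))
  s <- mode_epr(lam)
  expect_true(all(s >= 0))
  expect_equal(s == 0, Im(lam) == 0)
})

test_that("stationary mode correlators close the per-mode balance", {
  # real eigenvalue: velocity-field correlator vanishes
  cc <- stationary_mode_correlators(-2 + 0i, 1)
  expect_equal(cc$c_dot_star, 0 + 0i)
  expect_equal(cc$variance, 0.25)
  # frozen closed-form values at lambda = -1 + i, gamma = 2
  cc2 <- stationary_mode_correlators(-1 + 1i, 2)
  expect_equal(cc2$c_dot_star, 0 + 1i, tolerance = 1e-14)
  expect_equal(cc2$c_star_dot, 0 - 1i, tolerance = 1e-14)
  expect_equal(cc2$variance, 1)
  # the combination lambda <etadot* eta>/gamma + lambda* <etadot eta*>/gamma
  # equals the per-mode entropy production for random stable eigenvalues
  set.seed(5)
  for (i in 1:20) {
    lam <- complex(real = -runif(1, 0.1, 3), imaginary = rnorm(1))
    gk <- runif(1, 0.1, 5)
    cc3 <- stationary_mode_correlators(lam, gk)
    combo <- Re(lam * cc3$c_star_dot + Conj(lam) * cc3$c_dot_star) / gk
    expect_equal(combo, mode_epr(lam), tolerance = 1e-12)
    # correlators scale with gamma_k but their balance does not
    cc4 <- stationary_mode_correlators(lam, 2 * gk)
    expect_equal(cc4$c_dot_star, 2 * cc3$c_dot_star)
  }
})

test_that("spectral total vanishes for even kernels and matches the trace route", {
  m <- ring_model(32, "gaussian")
  nz <- white_noise_for(m)
  sp <- spectral_entropy_production(m, nz)
  expect_equal(sp$total_epr, 0)
  expect_true(all(sp$modes$gamma_k > 0))
  # asymmetric kernel: positive production, equal by both derivations
  ma <- ring_model(32, "shifted_gaussian", shift = pi / 4)
  spa <- spectral_entropy_production(ma, nz <- white_noise_for(ma))
  expect_gt(spa$total_epr, 0)
  s_trace <- entropy_production_trace(ma$drift_matrix, nz$covariance)
  expect_equal(spa$total_epr, s_trace, tolerance = 1e-8)
  # conjugate-pair symmetry of the per-mode rates
  for (mm in 1:15) {
    expect_equal(spa$modes$sigma_k[spa$modes$m == mm],
                 spa$modes$sigma_k[spa$modes$m == -mm])
  }
  # per-mode rates unchanged under correlated (still circulant) noise
  nzc <- build_noise(noise_spec("gaussian_correlated", amplitude = 1,
                                corr_length = 0.4), ma$grid)
  spc <- spectral_entropy_production(ma, nzc)
  expect_equal(spc$modes$sigma_k, spa$modes$sigma_k, tolerance = 1e-12)
  expect_equal(spc$total_epr, spa$total_epr, tolerance = 1e-12)
})

test_that("smallest complex ring: three-site shift kernel", {
  g <- discrete_grid(3, length = 3)
  m <- build_model(g, 1, sigmoid(2, 0.5),
                   kernel_spec("pure_shift", shift = 1, amplitude = 0.6))
  sp <- spectral_entropy_production(m, white_noise_for(m))
  ev <- sp$modes$lambda_k
  expect_gt(max(abs(Im(ev))), 0.1)
  expect_equal(sp$total_epr,
               entropy_production_trace(m$drift_matrix,
                                        white_noise_for(m)$covariance),
               tolerance = 1e-10)
})
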