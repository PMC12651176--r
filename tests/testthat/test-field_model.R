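test_that("sigmoid activation matches its closed form and limits", {
  act <- sigmoid(beta = 2, u_star = 0.5)
  expect_equal(sigmoid_activation(0.5, act), 0.5)
  expect_equal(sigmoid_activation(0, act), 1 / (exp(1) + 1), tolerance = 1e-14)
  # saturation at steep gain, and numerical stability far in the tails
  steep <- sigmoid(beta = 1e3, u_star = 0.5)
  expect_equal(sigmoid_activation(1.5, steep), 1, tolerance = 1e-12)
  expect_true(sigmoid_activation(-50, steep) >= 0)
  expect_true(is.finite(sigmoid_activation(1e6, steep)))
  # monotone increasing
  u <- seq(-3, 3, length.out = 101)
  expect_true(all(diff(sigmoid_activation(u, act)) > 0))
})

test_that("activation gain is the sigmoid derivative, symmetric and maximal at threshold", {
  act <- sigmoid(beta = 2, u_star = 0.5)
  expect_equal(activation_gain(0.5, act), 2 / 4)
  f0 <- 1 / (exp(1) + 1)
  expect_equal(activation_gain(0, act), 2 * f0 * (1 - f0), tolerance = 1e-14)
  expect_equal(activation_gain(0.5 + 0.3, act), activation_gain(0.5 - 0.3, act))
  # centered finite difference of the sigmoid, O(h^2)
  h <- 1e-6
  for (u in c(-1, 0, 0.5, 2)) {
    fd <- (sigmoid_activation(u + h, act) - sigmoid_activation(u - h, act)) / (2 * h)
    expect_equal(activation_gain(u, act), fd, tolerance = 1e-7)
  }
})

test_that("homogeneous fixed points solve f(u0) = u0 / w_tilde", {
  act <- sigmoid(beta = 2, u_star = 0.5)
  # threshold symmetry: u0 = 0.5 solves the equation at w_tilde = 1
  r <- solve_homogeneous_fixed_point(1, act)
  expect_true(any(abs(r$root - 0.5) < 1e-12))
  # residuals at stated tolerance
  for (w in c(0.3, 1, 2.5, -0.7)) {
    rr <- solve_homogeneous_fixed_point(w, act)
    expect_true(all(abs(w * sigmoid_activation(rr$root, act) - rr$root) <= 1e-12))
  }
  # w_tilde = 0 gives the single trivial root
  expect_equal(solve_homogeneous_fixed_point(0, act)$root, 0)
  # near-flat sigmoid: u0 -> w_tilde / 2
  flat <- sigmoid(beta = 1e-6, u_star = 0.5)
  expect_equal(solve_homogeneous_fixed_point(2, flat)$root, 1, tolerance = 1e-4)
})

test_that("steep sigmoid is bistable with outer roots stable", {
  act <- sigmoid(beta = 20, u_star = 0.5)
  r <- solve_homogeneous_fixed_point(1, act)
  # independent oracle: sign-change count of g(u) = f(u) - u on a fine grid
  u <- seq(-1, 2, length.out = 10000)
  gu <- 1 / (exp(20 * (0.5 - u)) + 1) - u
  expect_equal(sum(diff(sign(gu)) != 0), 3L)
  expect_equal(nrow(r), 3L)
  expect_equal(r$stable, c(TRUE, FALSE, TRUE))
})

test_that("linear operator discretizes the drift kernel with the stated convention", {
  g <- discrete_grid(4, length = 4)  # dx = 1
  expect_equal(build_linear_operator(g, tau = 2, matrix(0, 4, 4), 1),
               -diag(4) / 2)
  # direct substitution, 2 sites, dx = 1
  g2 <- discrete_grid(2, length = 2)
  W <- matrix(c(0, 0.3, 0.2, 0), 2, 2)
  expect_equal(build_linear_operator(g2, 1, W, 1),
               matrix(c(-1, 0.3, 0.2, -1), 2, 2))
  # symmetric kernel gives a self-adjoint drift with a real spectrum
  m <- ring_model(16, "gaussian")
  expect_equal(m$drift_matrix, t(m$drift_matrix))
  ev <- eigen(m$drift_matrix, only.values = TRUE)$values
  expect_true(all(abs(Im(ev)) < 1e-12))
  # unstable drift is refused
  expect_error(build_linear_operator(g, 1, diag(4) * 10, 1), "stable")
})

test_that("assembled models satisfy their invariants", {
  for (fam in c("gaussian", "shifted_gaussian", "mexican_hat")) {
    m <- ring_model(16, fam, shift = if (fam == "shifted_gaussian") 0.7 else 0)
    expect_lt(max(Re(eigen(m$drift_matrix, only.values = TRUE)$values)), -1e-10)
    resid <- abs(m$fixed_point -
                   m$row_integral * sigmoid_activation(m$fixed_point, m$activation))
    expect_lte(resid, 1e-12)
  }
  # zero coupling: drift is pure leak, u0 = 0
  g <- discrete_grid(8)
  m0 <- build_model(g, 2, sigmoid(2, 0.5), kernel_spec("zero"))
  expect_equal(m0$drift_matrix, -diag(8) / 2)
  expect_equal(m0$fixed_point, 0)
  # kernels without constant row sums admit no homogeneous fixed point
  W <- matrix(rnorm(64), 8, 8)
  expect_error(build_model(g, 1, sigmoid(2, 0.5), W), "homogeneous")
})

test_that("fixed-point selector picks the requested root", {
  g <- discrete_grid(4)
  act <- sigmoid(20, 0.5)
  roots <- solve_homogeneous_fixed_point(1, act)$root
  m_hi <- build_model(g, 1, act, kernel_spec("gaussian", width = 1,
                                             normalization = 1))
  expect_equal(m_hi$fixed_point, max(roots))
  m_lo <- build_model(g, 1, act, kernel_spec("gaussian", width = 1,
                                             normalization = 1),
                      fixed_point = "smallest")
  expect_equal(m_lo$fixed_point, min(roots))
  m_near <- build_model(g, 1, act, kernel_spec("gaussian", width = 1,
                                               normalization = 1),
                        fixed_point = 0.1)
  expect_equal(m_near$fixed_point, roots[which.min(abs(roots - 0.1))])
  # the middle root of the bistable equation is unstable: linearizing there
  # must be refused
  expect_error(build_model(g, 1, act,
                           kernel_spec("gaussian", width = 1,
                                       normalization = 1),
                           fixed_point = 0.5),
               "stable")
})

test_that("potential energy is the quadratic form of the self-adjoint drift", {
  m <- ring_model(12, "gaussian")
  expect_equal(potential_energy(m, numeric(12)), 0)
  # single-site analogue: U = eta^2 / (2 tau) at dx = 1
  g1 <- discrete_grid(1, length = 1)
  m1 <- build_model(g1, 2, sigmoid(2, 0.5), kernel_spec("zero"))
  expect_equal(potential_energy(m1, 1.5), 1.5^2 / 4)
  # independent eigenbasis evaluation of the same quadratic form
  set.seed(42)
  eta <- rnorm(12)
  e <- eigen(m$drift_matrix, symmetric = TRUE)
  y <- crossprod(e$vectors, eta)
  u_eig <- -0.5 * m$grid$spacing * sum(e$values * y^2)
  expect_equal(potential_energy(m, eta), u_eig, tolerance = 1e-12)
  expect_gt(potential_energy(m, eta), 0)
  # undefined for asymmetric drift
  ma <- ring_model(12, "shifted_gaussian", shift = 0.7)
  expect_error(potential_energy(ma, rnorm(12)), "self-adjoint")
})
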