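# Shared model builders for the test suite. Everything is generated in code;
# no stored fixtures.

# Planar rotation drift -a*I + b*J (J the symplectic unit), eigenvalues
# -a +/- i b. With isotropic noise its entropy production rate is 2 b^2 / a.
rotation_drift <- function(a = 1, b = 1) {
  matrix(c(-a, b, -b, -a), 2, 2)
}

# Random strictly stable drift: symmetric negative-definite part bounds all
# eigenvalue real parts below -margin, plus a random antisymmetric part.
random_stable_drift <- function(n, margin = 0.5, asym = 1) {
  M <- matrix(rnorm(n * n), n, n)
  S <- -(tcrossprod(M) / n + margin * diag(n))
  A <- matrix(rnorm(n * n), n, n)
  S + asym * (A - t(A)) / 2
}

# Random symmetric positive-definite covariance with eigenvalues in
# [lo, hi] (well-conditioned by construction).
random_spd <- function(n, lo = 0.5, hi = 2) {
  Q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  Q %*% diag(runif(n, lo, hi), n) %*% t(Q)
}

# Standard ring models used across tests.
ring_model <- function(n = 16, family = "gaussian", tau = 1, beta = 2,
                       u_star = 0.5, width = 0.5, shift = 0,
                       normalization = 1, L = 2 * pi) {
  g <- discrete_grid(n, L)
  build_model(g, tau, sigmoid(beta, u_star),
              kernel_spec(family, width = width, shift = shift,
                          normalization = normalization))
}

white_noise_for <- function(model, amplitude = 1) {
  build_noise(noise_spec("white", amplitude = amplitude), model$grid)
}
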