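#' Homogeneous fixed points of the neural field
#'
#' Solves `f(u0) = u0 / w_tilde` (equivalently `u0 = w_tilde * f(u0)`), the
#' self-consistency equation for spatially uniform stationary solutions of the
#' nonlinear field equation, where `w_tilde` is the row integral of the
#' synaptic kernel. Roots are located by a sign-change scan of
#' `g(u) = w_tilde * f(u) - u` on the bracket
#' `[min(0, w_tilde) - 1, max(0, w_tilde) + 1]` (safe because `0 < f < 1`
#' confines every root to lie between 0 and `w_tilde`), then polished with
#' [stats::uniroot()] and a Newton step to residual `<= 1e-12`.
#'
#' Each root is annotated with the local stability of the homogeneous ODE:
#' stable iff `-1 + w_tilde * f'(u0) < 0`.
#'
#' @param row_integral Real, the kernel row integral `w_tilde`.
#' @param act An [sigmoid()] object.
#' @param n_scan Number of scan points for sign-change bracketing.
#' @param tol Absolute residual tolerance for accepted roots.
#' @return A data frame with columns `root` and `stable`, ordered by `root`.
#'   For `w_tilde = 0` the single root 0 is returned. If the scan finds no
#'   sign change, an empty data frame is returned with a warning.
#' @examples
#' solve_homogeneous_fixed_point(1, sigmoid(20, 0.5))  # bistable: three roots
#' @export
solve_homogeneous_fixed_point <- function(row_integral, act,
                                          n_scan = 10000L, tol = 1e-12) {
  stopifnot(is.numeric(row_integral), length(row_integral) == 1L,
            is.finite(row_integral), inherits(act, "amari_sigmoid"))
  stable_flag <- function(u) (-1 + row_integral * activation_gain(u, act)) < 0
  if (row_integral == 0) {
    return(data.frame(root = 0, stable = stable_flag(0)))
  }
  lo <- min(0, row_integral) - 1
  hi <- max(0, row_integral) + 1
  g <- function(u) row_integral * sigmoid_activation(u, act) - u
  us <- seq(lo, hi, length.out = n_scan)
  gs <- g(us)
  roots <- numeric(0)
  exact <- which(gs == 0)
  roots <- c(roots, us[exact])
  flips <- which(gs[-1] * gs[-n_scan] < 0)
  for (i in flips) {
    r <- uniroot(g, lower = us[i], upper = us[i + 1], tol = 1e-14)$root
    # Newton polish: g'(u) = w_tilde * f'(u) - 1
    for (it in 1:5) {
      gr <- row_integral * activation_gain(r, act) - 1
      if (abs(gr) < .Machine$double.eps) break
      step <- g(r) / gr
      r <- r - step
      if (abs(step) < tol / 10) break
    }
    if (abs(g(r)) <= tol) roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0L) {
    warning("no fixed-point root found in the search bracket")
    return(data.frame(root = numeric(0), stable = logical(0)))
  }
  data.frame(root = roots, stable = vapply(roots, stable_flag, logical(1)))
}

#' Linearized drift operator as a matrix
#'
#' Discretizes the drift kernel of the fluctuation dynamics,
#' `lambda(x, y) = -delta(x - y) / tau + f'(u0) * w(x, y) / tau`, with the
#' package-wide quadrature convention: the Dirac delta contributes `-1/tau`
#' on the diagonal with no quadrature weight, the smooth synaptic kernel
#' carries the weight `dx`, giving
#' `Lambda[i, j] = -delta_ij / tau + (gain / tau) * W[i, j] * dx`.
#'
#' @param grid An [discrete_grid()] object.
#' @param tau Positive real relaxation time.
#' @param kernel_matrix Square matrix of kernel values `w(x_i, x_j)`.
#' @param gain_at_fp Real, `f'(u0)` at the homogeneous fixed point.
#' @param check_stability If `TRUE` (default), error unless every eigenvalue
#'   has real part `< -1e-10`.
#' @return The drift matrix `Lambda`.
#' @examples
#' g <- discrete_grid(4)
#' build_linear_operator(g, tau = 2, matrix(0, 4, 4), gain_at_fp = 1)
#' @export
build_linear_operator <- function(grid, tau, kernel_matrix, gain_at_fp,
                                  check_stability = TRUE) {
  stopifnot(inherits(grid, "amari_grid"), is.numeric(tau), tau > 0)
  assert_square(kernel_matrix)
  if (nrow(kernel_matrix) != grid$n_points) {
    stop("kernel matrix dimension does not match the grid", call. = FALSE)
  }
  drift <- (gain_at_fp / tau) * kernel_matrix * grid$spacing
  diag(drift) <- diag(drift) - 1 / tau
  if (check_stability) {
    ev <- eigen(drift, only.values = TRUE)$values
    worst <- ev[which.max(Re(ev))]
    if (Re(worst) >= -1e-10) {
      stop(sprintf(
        "drift operator is not strictly stable: eigenvalue %g%+gi has real part >= -1e-10",
        Re(worst), Im(worst)), call. = FALSE)
    }
  }
  drift
}

#' Assemble a linearized stochastic neural field model
#'
#' Checks that the kernel admits a homogeneous fixed point (row sums times
#' `dx` constant across rows to relative tolerance `1e-8`), computes the row
#' integral `w_tilde`, solves the fixed-point equation, selects one root,
#' evaluates the gain `f'(u0)` there, and builds the stable linearized drift
#' matrix.
#'
#' @param grid An [discrete_grid()] object.
#' @param tau Positive real relaxation time.
#' @param act An [sigmoid()] object.
#' @param kernel Either a square kernel matrix `w(x_i, x_j)` or a
#'   [kernel_spec()] to be realized on `grid`.
#' @param fixed_point Root selection rule when the fixed-point equation is
#'   multistable: `"largest"` (default) or `"smallest"` pick among stable
#'   roots; a number picks the root nearest that value; an integer wrapped in
#'   `I()` picks by index in the sorted root list.
#' @return An object of class `amari_model`: list with elements `grid`,
#'   `tau`, `activation`, `kernel_matrix`, `row_integral`, `fixed_point`,
#'   `gain_at_fp`, `drift_matrix`, `fixed_points` (the full annotated root
#'   set).
#' @examples
#' g <- discrete_grid(16)
#' m <- build_model(g, tau = 1, sigmoid(2, 0.5),
#'                  kernel_spec("gaussian", amplitude = 0.5, width = 1))
#' max(Re(eigen(m$drift_matrix)$values)) < 0
#' @export
build_model <- function(grid, tau, act, kernel, fixed_point = "largest") {
  stopifnot(inherits(grid, "amari_grid"), inherits(act, "amari_sigmoid"),
            is.numeric(tau), length(tau) == 1L, tau > 0)
  if (inherits(kernel, "amari_kernel_spec")) {
    kernel <- build_kernel(kernel, grid)
  }
  assert_square(kernel, "kernel")
  rs <- rowSums(kernel) * grid$spacing
  w_tilde <- mean(rs)
  spread <- max(abs(rs - w_tilde))
  if (spread > 1e-8 * (1 + abs(w_tilde))) {
    stop("no homogeneous fixed point: kernel row integrals are not constant",
         call. = FALSE)
  }
  roots <- solve_homogeneous_fixed_point(w_tilde, act)
  if (nrow(roots) == 0L) {
    stop("no homogeneous fixed point found", call. = FALSE)
  }
  u0 <- select_fixed_point(roots, fixed_point)
  gain <- activation_gain(u0, act)
  drift <- build_linear_operator(grid, tau, kernel, gain)
  structure(
    list(grid = grid, tau = tau, activation = act, kernel_matrix = kernel,
         row_integral = w_tilde, fixed_point = u0, gain_at_fp = gain,
         drift_matrix = drift, fixed_points = roots),
    class = "amari_model")
}

select_fixed_point <- function(roots, selector) {
  stable <- roots[roots$stable, , drop = FALSE]
  if (inherits(selector, "AsIs")) {
    i <- as.integer(selector)
    if (i < 1L || i > nrow(roots)) stop("fixed-point index out of range")
    return(roots$root[i])
  }
  if (is.numeric(selector)) {
    return(roots$root[which.min(abs(roots$root - selector))])
  }
  pool <- if (nrow(stable) > 0L) stable else roots
  switch(match.arg(selector, c("largest", "smallest")),
         largest = max(pool$root),
         smallest = min(pool$root))
}

#' @export
print.amari_model <- function(x, ...) {
  ev <- eigen(x$drift_matrix, only.values = TRUE)$values
  cat("Linearized stochastic neural field model\n")
  cat(sprintf("  grid: %d points, L = %g; tau = %g\n",
              x$grid$n_points, x$grid$length, x$tau))
  cat(sprintf("  w_tilde = %g, u0 = %g, f'(u0) = %g\n",
              x$row_integral, x$fixed_point, x$gain_at_fp))
  cat(sprintf("  drift spectrum: Re in [%g, %g], max |Im| = %g\n",
              min(Re(ev)), max(Re(ev)), max(abs(Im(ev)))))
  invisible(x)
}

#' Quadratic potential of the self-adjoint field
#'
#' For a symmetric (self-adjoint) drift operator the linear dynamics are a
#' gradient flow in the potential
#' `U(eta) = -(dx^2 / 2) * sum_ij eta_i lambda(x_i, x_j) eta_j`, evaluated
#' here with the same discretization convention as [build_linear_operator()]
#' (so the delta part contributes `eta^2 / (2 * tau) * dx` per site). For a
#' stable symmetric drift, `U >= 0` with equality iff `eta = 0`, and with
#' spatially white noise the stationary density is the Boltzmann weight
#' `exp(-U / T)`.
#'
#' @param model An [build_model()] object with symmetric drift.
#' @param field Numeric vector `eta` on the model grid.
#' @return The potential energy, a nonnegative scalar.
#' @export
potential_energy <- function(model, field) {
  stopifnot(inherits(model, "amari_model"))
  drift <- model$drift_matrix
  if (frobenius(drift - t(drift)) > 1e-10 * (1 + frobenius(drift))) {
    stop("potential undefined for non-self-adjoint drift", call. = FALSE)
  }
  stopifnot(length(field) == model$grid$n_points)
  dx <- model$grid$spacing
  # operator-matrix convention: Lambda already carries one factor of dx on
  # its smooth part, so the double space integral contributes one more dx
  -0.5 * dx * sum(field * (drift %*% field))
}
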