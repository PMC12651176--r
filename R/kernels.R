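#' Parametric synaptic kernel specification
#'
#' Families of translation-invariant synaptic profiles `w(x - y)` on the
#' periodic domain, realized as circulant matrices by [build_kernel()] using
#' the signed minimum-image displacement on the ring. Available families:
#'
#' * `"zero"`: no coupling.
#' * `"gaussian"`: `amplitude * exp(-d^2 / (2 width^2))`; even, hence a
#'   symmetric matrix (reversible coupling).
#' * `"shifted_gaussian"`: `amplitude * exp(-(d - shift)^2 / (2 width^2))`;
#'   `shift != 0` breaks the parity of the profile and makes the coupling
#'   matrix asymmetric — the minimal irreversible kernel.
#' * `"mexican_hat"`: difference of Gaussians,
#'   `amplitude * (exp(-d^2 / (2 width^2)) -
#'   ratio * exp(-d^2 / (2 (surround * width)^2)))`; local excitation with
#'   broader inhibition, even and symmetric.
#' * `"pure_shift"`: a discrete displacement by `shift` (placed at the
#'   nearest lattice offset), profile `amplitude / dx` at that offset; the
#'   maximally asymmetric coupling whose Fourier transform does not decay.
#' * `"explicit_matrix"`: pass `matrix` through (validated).
#'
#' @param family One of the family names above.
#' @param amplitude Profile amplitude (default 1).
#' @param width Positive real, Gaussian width `l` (families with a profile).
#' @param shift Real displacement `s` for `shifted_gaussian` / `pure_shift`.
#' @param ratio Inhibition/excitation amplitude ratio for `mexican_hat`
#'   (default 0.3; note `ratio * surround = 1` makes the row integral vanish,
#'   which precludes normalization).
#' @param surround Surround/center width ratio for `mexican_hat` (default 2).
#' @param matrix Explicit square matrix for `explicit_matrix`.
#' @param normalization Optional target row integral `w_tilde`; the realized
#'   matrix is rescaled so that `dx * rowSums` equals this value.
#' @return An object of class `amari_kernel_spec`.
#' @seealso [build_kernel()], [noise_spec()]
#' @export
kernel_spec <- function(family = c("zero", "gaussian", "shifted_gaussian",
                                   "mexican_hat", "pure_shift",
                                   "explicit_matrix"),
                        amplitude = 1, width = NULL, shift = 0,
                        ratio = 0.3, surround = 2, matrix = NULL,
                        normalization = NULL) {
  family <- match.arg(family)
  if (family %in% c("gaussian", "shifted_gaussian", "mexican_hat")) {
    if (is.null(width) || !is.numeric(width) || width <= 0) {
      stop("'width' must be a positive real for this kernel family",
           call. = FALSE)
    }
  }
  if (family == "explicit_matrix") {
    if (is.null(matrix)) stop("'matrix' required for explicit_matrix family",
                              call. = FALSE)
    assert_square(matrix)
  }
  structure(list(family = family, amplitude = amplitude, width = width,
                 shift = shift, ratio = ratio, surround = surround,
                 matrix = matrix, normalization = normalization),
            class = "amari_kernel_spec")
}

#' Realize a synaptic kernel on a grid
#'
#' Evaluates the profile of a [kernel_spec()] at the signed minimum-image
#' displacements of the periodic lattice and assembles the circulant matrix
#' `W[i, j] = w(x_i - x_j)`. With `normalization` set, the matrix is rescaled
#' so the row integral `dx * rowSums(W)` equals the target.
#'
#' @param spec A [kernel_spec()].
#' @param grid An [discrete_grid()].
#' @return A square numeric matrix of kernel values.
#' @examples
#' g <- discrete_grid(32)
#' W <- build_kernel(kernel_spec("gaussian", width = 0.5), g)
#' all.equal(W, t(W))   # even profile => symmetric coupling
#' @export
build_kernel <- function(spec, grid) {
  stopifnot(inherits(spec, "amari_kernel_spec"), inherits(grid, "amari_grid"))
  n <- grid$n_points
  L <- grid$length
  dx <- grid$spacing
  # profile at displacements +x_j (j = 0..n-1); even families use the
  # unsigned ring distance computed from index arithmetic so that
  # profile[m] == profile[n - m] holds exactly and the realized matrix is
  # exactly symmetric
  idx <- 0:(n - 1)
  d <- pmin(idx, n - idx) * dx
  profile <- switch(
    spec$family,
    zero = numeric(n),
    gaussian = spec$amplitude * exp(-d^2 / (2 * spec$width^2)),
    shifted_gaussian = {
      ds <- minimum_image(grid$positions - spec$shift, L)
      spec$amplitude * exp(-ds^2 / (2 * spec$width^2))
    },
    mexican_hat = spec$amplitude *
      (exp(-d^2 / (2 * spec$width^2)) -
         spec$ratio * exp(-d^2 / (2 * (spec$surround * spec$width)^2))),
    pure_shift = {
      p <- numeric(n)
      p[(round(spec$shift / dx) %% n) + 1L] <- spec$amplitude / dx
      p
    },
    explicit_matrix = NULL)
  W <- if (spec$family == "explicit_matrix") {
    m <- spec$matrix
    if (nrow(m) != n) stop("explicit kernel matrix does not match the grid",
                           call. = FALSE)
    m
  } else {
    circulant_from_profile(profile)
  }
  if (!is.null(spec$normalization)) {
    w_tilde <- mean(rowSums(W)) * dx
    if (abs(w_tilde) < 1e-14) {
      stop("cannot normalize a kernel with zero row integral", call. = FALSE)
    }
    W <- W * (spec$normalization / w_tilde)
  }
  W
}

#' Noise covariance specification
#'
#' Families of spatial noise covariance kernels `gamma(x, y)` for the
#' additive, white-in-time Gaussian forcing:
#'
#' * `"white"`: space-time white noise `gamma(x, y) = T * delta(x - y)`,
#'   realized on the lattice as `(T / dx) * I` (delta convention).
#' * `"gaussian_correlated"`: translation-invariant squared-exponential
#'   profile `T / (sqrt(2*pi) * corr_length) * exp(-d^2 / (2 corr_length^2))`
#'   (normalized so it tends to the white kernel as `corr_length -> 0`),
#'   with a diagonal jitter `<= 1e-10 * max(diag)` enforcing positive
#'   definiteness of the minimum-image discretization.
#' * `"explicit_matrix"`: pass a symmetric positive-definite matrix through.
#'
#' @param family One of `"white"`, `"gaussian_correlated"`,
#'   `"explicit_matrix"`.
#' @param amplitude Positive real noise strength `T`.
#' @param corr_length Positive real correlation length (correlated family).
#' @param matrix Explicit covariance matrix.
#' @return An object of class `amari_noise_spec`.
#' @export
noise_spec <- function(family = c("white", "gaussian_correlated",
                                  "explicit_matrix"),
                       amplitude = 1, corr_length = NULL, matrix = NULL) {
  family <- match.arg(family)
  if (!is.numeric(amplitude) || amplitude <= 0) {
    stop("'amplitude' (T) must be positive", call. = FALSE)
  }
  if (family == "gaussian_correlated" &&
      (is.null(corr_length) || corr_length <= 0)) {
    stop("'corr_length' must be a positive real", call. = FALSE)
  }
  if (family == "explicit_matrix" && is.null(matrix)) {
    stop("'matrix' required for explicit_matrix family", call. = FALSE)
  }
  structure(list(family = family, amplitude = amplitude,
                 corr_length = corr_length, matrix = matrix),
            class = "amari_noise_spec")
}

#' Realize a noise model on a grid
#'
#' Builds the symmetric positive-definite covariance matrix `Gamma` of the
#' spatial noise kernel together with its lower-triangular Cholesky factor
#' `B` (`B %*% t(B) = Gamma`), used for sampling.
#'
#' @param spec A [noise_spec()], or a symmetric positive-definite matrix
#'   (shorthand for an explicit covariance).
#' @param grid An [discrete_grid()].
#' @return An object of class `amari_noise`: list with `grid`,
#'   `covariance`, `factor`, and `white_amplitude` (`T` for the white family,
#'   otherwise `NA`).
#' @examples
#' g <- discrete_grid(16)
#' nm <- build_noise(noise_spec("white", amplitude = 2), g)
#' all(diag(nm$covariance) == 2 / g$spacing)
#' @export
build_noise <- function(spec, grid) {
  stopifnot(inherits(grid, "amari_grid"))
  if (is.matrix(spec)) spec <- noise_spec("explicit_matrix", matrix = spec)
  stopifnot(inherits(spec, "amari_noise_spec"))
  n <- grid$n_points
  white_amplitude <- NA_real_
  G <- switch(
    spec$family,
    white = {
      white_amplitude <- spec$amplitude
      diag(spec$amplitude / grid$spacing, n)
    },
    gaussian_correlated = {
      idx <- 0:(n - 1)
      d <- pmin(idx, n - idx) * grid$spacing   # exactly even profile
      prof <- spec$amplitude / (sqrt(2 * pi) * spec$corr_length) *
        exp(-d^2 / (2 * spec$corr_length^2))
      G0 <- circulant_from_profile(prof)
      G0 <- (G0 + t(G0)) / 2
      diag(G0) <- diag(G0) + 1e-10 * max(diag(G0))
      G0
    },
    explicit_matrix = {
      m <- spec$matrix
      if (nrow(m) != n) stop("explicit covariance does not match the grid",
                             call. = FALSE)
      assert_symmetric(m, "noise covariance", tol = 1e-10)
      (m + t(m)) / 2
    })
  B <- spd_factor(G, "noise covariance")
  structure(list(grid = grid, covariance = G, factor = B,
                 white_amplitude = white_amplitude),
            class = "amari_noise")
}

#' @export
print.amari_noise <- function(x, ...) {
  kind <- if (!is.na(x$white_amplitude)) {
    sprintf("white, T = %g", x$white_amplitude)
  } else "correlated"
  cat(sprintf("Spatial noise covariance (%s), %d x %d\n",
              kind, nrow(x$covariance), ncol(x$covariance)))
  invisible(x)
}
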