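#' @useDynLib amariepr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd uniroot plogis setNames
#' @importFrom utils write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

frobenius <- function(m) sqrt(sum(m^2))

is_square_matrix <- function(m) is.matrix(m) && nrow(m) == ncol(m)

assert_square <- function(m, name = deparse(substitute(m))) {
  if (!is_square_matrix(m) || !is.numeric(m)) {
    stop(sprintf("'%s' must be a square numeric matrix", name), call. = FALSE)
  }
  invisible(m)
}

assert_symmetric <- function(m, name = deparse(substitute(m)), tol = 1e-8) {
  assert_square(m, name)
  if (frobenius(m - t(m)) > tol * (1 + frobenius(m))) {
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  }
  invisible(m)
}

## Cholesky-based SPD inverse; errors with a clear message on non-PD input.
spd_inverse <- function(m, name = "matrix") {
  ch <- tryCatch(chol(m), error = function(e) {
    stop(sprintf("'%s' is not positive definite", name), call. = FALSE)
  })
  chol2inv(ch)
}

## Lower-triangular factor B with B %*% t(B) = m.
spd_factor <- function(m, name = "matrix") {
  ch <- tryCatch(chol(m), error = function(e) {
    stop(sprintf("'%s' is not positive definite", name), call. = FALSE)
  })
  t(ch)
}

## Max deviation of a matrix from circulant structure (row i is row 1 rolled
## by i-1), relative to the matrix norm.
circulant_deviation <- function(m) {
  n <- nrow(m)
  prof <- m[, 1]
  idx <- outer(seq_len(n), seq_len(n), function(i, j) ((i - j) %% n) + 1L)
  ref <- matrix(prof[idx], n, n)
  dev <- max(abs(m - ref))
  dev / max(max(abs(m)), .Machine$double.xmin)
}

assert_circulant <- function(m, name = deparse(substitute(m)), tol = 1e-10) {
  assert_square(m, name)
  if (circulant_deviation(m) > tol) {
    stop(sprintf("translational invariance required: '%s' is not circulant",
                 name), call. = FALSE)
  }
  invisible(m)
}

## Build a circulant matrix M[i, j] = profile[((i - j) mod n) + 1].
circulant_from_profile <- function(profile) {
  n <- length(profile)
  idx <- outer(seq_len(n), seq_len(n), function(i, j) ((i - j) %% n) + 1L)
  matrix(profile[idx], n, n)
}

## Cheap content fingerprint for matching trajectories to the (drift, noise)
## pair that generated them.
model_fingerprint <- function(drift, noise_cov) {
  paste0("n", nrow(drift),
         ":d", signif(sum(drift), 12), ",", signif(sum(drift^2), 12),
         ":g", signif(sum(noise_cov), 12), ",", signif(sum(noise_cov^2), 12))
}

max_real_eigenvalue <- function(m) max(Re(eigen(m, only.values = TRUE)$values))
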