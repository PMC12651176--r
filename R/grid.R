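#' Periodic one-dimensional spatial lattice
#'
#' Discretizes a boundary-free (periodic) one-dimensional domain of length
#' `L` into `n_points` equally spaced sites `x_i = i * dx`,
#' `i = 0, ..., n_points - 1`, with spacing `dx = L / n_points`. All fields,
#' synaptic kernels and noise kernels in the package live on such a ring;
#' index arithmetic is modulo `n_points` throughout.
#'
#' @param n_points Positive integer, number of lattice sites.
#' @param length Positive real, domain size `L`. Default `2 * pi`.
#'
#' @return An object of class `amari_grid`: a list with elements `n_points`,
#'   `length`, `spacing` and `positions`.
#' @examples
#' g <- discrete_grid(8, length = 4)
#' g$spacing            # 0.5
#' range(g$positions)   # positions lie in [0, L)
#' @export
discrete_grid <- function(n_points, length = 2 * pi) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 1 ||
      n_points != round(n_points)) {
    stop("'n_points' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(length) || length(length) != 1L || length <= 0) {
    stop("'length' must be a positive real", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  spacing <- length / n_points
  structure(
    list(n_points = n_points,
         length = length,
         spacing = spacing,
         positions = spacing * (seq_len(n_points) - 1)),
    class = "amari_grid")
}

#' @export
print.amari_grid <- function(x, ...) {
  cat(sprintf("Periodic 1-d grid: %d points, L = %g, dx = %g\n",
              x$n_points, x$length, x$spacing))
  invisible(x)
}

## Signed minimum-image displacement on the ring, in (-L/2, L/2].
minimum_image <- function(d, L) {
  d - L * round(d / L)
}
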