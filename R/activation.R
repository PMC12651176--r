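#' Sigmoid activation parameters
#'
#' The firing-rate nonlinearity of the neural field,
#' `f(u) = 1 / (exp(beta * (u_star - u)) + 1)`: a logistic sigmoid with gain
#' `beta` and activation threshold `u_star`. Large `beta` approaches a hard
#' threshold; `f(u_star) = 1/2` always.
#'
#' @param beta Positive real, sigmoid gain.
#' @param u_star Positive real, activation threshold.
#' @return An object of class `amari_sigmoid`.
#' @examples
#' act <- sigmoid(beta = 2, u_star = 0.5)
#' sigmoid_activation(0.5, act)  # 0.5 at threshold
#' @export
sigmoid <- function(beta, u_star) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop("'beta' must be a positive real", call. = FALSE)
  }
  if (!is.numeric(u_star) || length(u_star) != 1L || u_star <= 0) {
    stop("'u_star' must be a positive real", call. = FALSE)
  }
  structure(list(beta = beta, u_star = u_star), class = "amari_sigmoid")
}

#' @export
print.amari_sigmoid <- function(x, ...) {
  cat(sprintf("Sigmoid activation: gain beta = %g, threshold u* = %g\n",
              x$beta, x$u_star))
  invisible(x)
}

#' Evaluate the sigmoid activation
#'
#' Numerically stable for arbitrarily large `|beta * (u_star - u)|` (via
#' [stats::plogis()], which branches on the sign of the argument).
#'
#' @param u Numeric vector of field values.
#' @param act An [sigmoid()] object.
#' @return `f(u)` in `(0, 1)`, monotonically increasing in `u`.
#' @export
sigmoid_activation <- function(u, act) {
  stopifnot(inherits(act, "amari_sigmoid"))
  plogis(act$beta * (u - act$u_star))
}

#' Slope of the sigmoid activation
#'
#' Returns `df/du = beta * f * (1 - f)`, the gain of the nonlinearity. It is
#' strictly positive, maximal (`beta / 4`) at the threshold, and symmetric
#' about it. Evaluated at the homogeneous fixed point it is the coefficient
#' that enters the linearized drift operator.
#'
#' @inheritParams sigmoid_activation
#' @return `df/du`, a numeric vector.
#' @export
activation_gain <- function(u, act) {
  stopifnot(inherits(act, "amari_sigmoid"))
  z <- act$beta * (u - act$u_star)
  # f * (1 - f) = plogis(z) * plogis(-z), stable for large |z|
  act$beta * plogis(z) * plogis(-z)
}
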