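# Cayley parameterization of SO(d): P = (1 - Q)(1 + Q)^-1 with Q antisymmetric.
# Q is carried as its strictly-lower-triangular parameters; the chart covers
# SO(d) up to a measure-zero set (P with eigenvalue -1), which an optimizer
# started at Q = 0 does not meet in practice.

#' Expand strictly-lower-triangle parameters to an antisymmetric matrix
#'
#' @param params numeric vector of length d(d-1)/2 (column-major strict lower
#'   triangle), or an antisymmetric matrix passed through unchanged.
#' @param d matrix dimension (required when `params` is a vector).
#' @return d x d antisymmetric matrix.
#' @export
antisymmetric <- function(params, d = NULL) {
  if (is.matrix(params)) {
    if (max(abs(params + t(params))) > 1e-12 * max(1, max(abs(params)))) {
      stop("matrix is not antisymmetric")
    }
    return((params - t(params)) / 2)  # exact antisymmetry
  }
  if (is.null(d)) stop("d is required when parameters are a vector")
  if (length(params) != d * (d - 1) / 2) stop("wrong parameter count for dimension d")
  Q <- matrix(0, d, d)
  Q[lower.tri(Q)] <- params
  Q - t(Q)
}

# inverse of antisymmetric(): strict lower triangle as a vector
antisymmetric_params <- function(Q) Q[lower.tri(Q)]

#' Cayley transform
#'
#' Maps an antisymmetric generator Q to the special orthogonal matrix
#' P = (1 - Q)(1 + Q)^-1. For real antisymmetric Q the eigenvalues of 1 + Q
#' are 1 + i*omega, so the inverse always exists; the two operator orders
#' commute because both factors are rational functions of Q.
#'
#' @param q antisymmetric matrix, or parameter vector with `d` supplied.
#' @param d dimension when `q` is a parameter vector.
#' @return d x d matrix in SO(d).
#' @export
cayley <- function(q, d = NULL) {
  Q <- antisymmetric(q, d)
  n <- nrow(Q)
  (diag(n) - Q) %*% solve(diag(n) + Q)
}

#' Fourier spectral second-derivative operator
#'
#' Periodic spectral differentiation matrix for twice differentiation on d
#' uniformly spaced points of a unit-length interval: the DFT conjugation of
#' the diagonal -(2 pi k)^2, with the Nyquist mode included. Real, symmetric,
#' and exact for resolvable harmonics; rows sum to zero.
#'
#' @param d number of grid points, even and at least 4.
#' @return d x d real matrix of class `second_derivative_operator`.
#' @export
spectral_second_derivative <- function(d) {
  d <- as.integer(d)
  if (d < 4L || d %% 2L != 0L) {
    stop("the periodic spectral operator is built for even d >= 4")
  }
  k <- c(0:(d / 2), -((d / 2 - 1):1))
  ev <- -(2 * pi * k)^2
  Fm <- exp(-2i * pi * outer(0:(d - 1), 0:(d - 1)) / d)
  D2 <- Re(Conj(Fm) %*% (ev * Fm) / d)
  structure(D2, class = c("second_derivative_operator", "matrix", "array"))
}

#' Tikhonov smoothness functional
#'
#' Squared Frobenius norm of the second derivative of the signal columns,
#' Lambda(V) = ||D V||_F^2; additive over columns.
#'
#' @param V numeric matrix (or vector) of signal columns.
#' @param D a [spectral_second_derivative()] operator matching `nrow(V)`.
#' @return nonnegative scalar.
#' @export
tikhonov_norm <- function(V, D) {
  if (is.vector(V)) V <- matrix(V, ncol = 1)
  if (nrow(V) != nrow(D)) stop("signal length does not match the operator")
  sum((unclass(D) %*% V)^2)
}
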