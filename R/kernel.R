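#' Dipolar coupling constant
#'
#' Angular frequency of the secular electron-electron dipolar interaction for
#' an isolated spin pair, D = mu0 gamma_e^2 hbar / (4 pi r^3), converted to
#' rad per microsecond for r in nm. This is the inverse-cube law that makes
#' DEER a molecular ruler: 2 nm corresponds to about 6.5 MHz.
#'
#' @param r inter-electron distance in nm, strictly positive (vectorized).
#' @return angular frequency in rad us^-1.
#' @export
dipolar_coupling <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("distance must be positive")
  cst <- physical_constants()
  # SI value in rad/s for r in metres, then nm and microseconds
  cst$mu0 / (4 * pi) * cst$gamma_e^2 * cst$hbar / (r * 1e-9)^3 * 1e-6
}

#' Dipolar kernel value
#'
#' Orientation-averaged ("powder") dipolar evolution function of a spin pair,
#' gamma(r, t) = sqrt(pi/(6 D t)) * (cos(Dt) C(sqrt(6Dt/pi)) +
#' sin(Dt) S(sqrt(6Dt/pi))), with C and S the normalized Fresnel integrals.
#' Equivalent to the average of cos((3 cos^2 theta - 1) D t) over a uniform
#' orientation distribution. At t = 0 the analytic limit 1 is returned; below
#' Dt = 1e-6 the series limit is used to avoid 0/0.
#'
#' @param r distance in nm, positive.
#' @param t time in us, nonnegative (vectorized over both, recycled).
#' @return unitless amplitude in \[-1, 1\].
#' @export
kernel_value <- function(r, t) {
  if (any(t < 0)) stop("time must be nonnegative")
  x <- dipolar_coupling(r) * t
  out <- rep(1, length(x))
  big <- x >= 1e-6
  if (any(big)) {
    xb <- x[big]
    arg <- sqrt(6 * xb / pi)
    out[big] <- sqrt(pi / (6 * xb)) *
      (cos(xb) * pracma::fresnelC(arg) + sin(xb) * pracma::fresnelS(arg))
  }
  out
}

#' Discretized dipolar kernel matrix
#'
#' Builds the n_time x n_dist matrix K with K\[i, j\] = gamma(r_j, t_i) that
#' links distance space to time space in the Fredholm integral.
#'
#' @param dgrid a [distance_grid()].
#' @param tgrid a [time_grid()].
#' @return An object of class `dipolar_kernel` with fields `matrix`, `dgrid`,
#'   `tgrid`.
#' @export
build_kernel <- function(dgrid, tgrid) {
  stopifnot(inherits(dgrid, "distance_grid"), inherits(tgrid, "time_grid"))
  m <- outer(tgrid$t, dgrid$r, function(t, r) kernel_value(r, t))
  structure(list(matrix = m, dgrid = dgrid, tgrid = tgrid),
            class = "dipolar_kernel")
}

#' @export
print.dipolar_kernel <- function(x, ...) {
  cat("Dipolar kernel: ", x$tgrid$n, " time points x ", x$dgrid$n,
      " distance points\n", sep = "")
  invisible(x)
}

#' Fredholm forward transform
#'
#' Maps a distance distribution p(r) to the clean dipolar form factor
#' Gamma(t) = integral of p(r) gamma(r, t) dr, by trapezoidal quadrature on
#' the kernel's distance grid.
#'
#' @param p a [distance_distribution()] on the kernel's distance grid.
#' @param k a [dipolar_kernel()].
#' @return A [deer_trace()] of kind `clean_form_factor`.
#' @export
fredholm_forward <- function(p, k) {
  stopifnot(inherits(p, "distance_distribution"), inherits(k, "dipolar_kernel"))
  if (!identical(p$grid$n, k$dgrid$n) ||
      abs(p$grid$r_min - k$dgrid$r_min) > 1e-12 ||
      abs(p$grid$r_max - k$dgrid$r_max) > 1e-12) {
    stop("distribution grid does not match the kernel's distance grid")
  }
  w <- trapezoid_weights(k$dgrid$r)
  deer_trace(as.numeric(k$matrix %*% (w * p$values)), k$tgrid,
             kind = "clean_form_factor")
}
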