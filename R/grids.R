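#' Physical constants for the dipolar coupling
#'
#' CODATA values of the vacuum permeability, the reduced Planck constant and
#' the electron magnetogyric ratio, all in SI units. Both electrons of a
#' nitroxide-type spin pair carry the free-electron magnetogyric ratio.
#'
#' @return A list with elements `mu0` (N A^-2), `hbar` (J s) and
#'   `gamma_e` (rad s^-1 T^-1).
#' @export
physical_constants <- function() {
  list(
    mu0     = 4e-7 * pi,          # vacuum permeability
    hbar    = 1.054571817e-34,    # reduced Planck constant
    gamma_e = 1.76085963023e11    # electron magnetogyric ratio
  )
}

#' Uniform distance grid
#'
#' @param r_min,r_max grid limits in nm, `0 < r_min < r_max`.
#' @param n number of points, at least 2.
#' @return An object of class `distance_grid` with the point vector `r`.
#' @export
distance_grid <- function(r_min, r_max, n) {
  stopifnot(is.numeric(r_min), is.numeric(r_max), is.numeric(n))
  if (!(r_min > 0 && r_max > r_min)) {
    stop("distance grid requires 0 < r_min < r_max")
  }
  n <- as.integer(n)
  if (n < 2L) stop("distance grid needs at least 2 points")
  structure(
    list(r = seq(r_min, r_max, length.out = n),
         r_min = r_min, r_max = r_max, n = n),
    class = "distance_grid"
  )
}

#' Uniform time grid starting at zero
#'
#' @param t_max last time point in microseconds, positive.
#' @param n number of points, at least 2; the first point is exactly 0.
#' @return An object of class `time_grid` with the point vector `t`.
#' @export
time_grid <- function(t_max, n) {
  if (!(is.numeric(t_max) && t_max > 0)) stop("t_max must be positive")
  n <- as.integer(n)
  if (n < 2L) stop("time grid needs at least 2 points")
  structure(
    list(t = seq(0, t_max, length.out = n), t_max = t_max, n = n),
    class = "time_grid"
  )
}

# trapezoidal quadrature weights on a uniform grid
trapezoid_weights <- function(x) {
  n <- length(x)
  h <- x[2] - x[1]
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  w
}

#' Distance probability density on a grid
#'
#' A nonnegative density per nm whose trapezoidal integral over the grid is 1.
#'
#' @param values density values, one per grid point.
#' @param grid a [distance_grid()].
#' @param normalize renormalize `values` to unit integral before validation.
#' @return An object of class `distance_distribution`.
#' @export
distance_distribution <- function(values, grid, normalize = FALSE) {
  stopifnot(inherits(grid, "distance_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n) stop("value count does not match the grid")
  if (any(values < 0)) stop("density values must be nonnegative")
  w <- trapezoid_weights(grid$r)
  mass <- sum(w * values)
  if (normalize) {
    if (mass <= 0) stop("cannot normalize a zero density")
    values <- values / mass
  } else if (abs(mass - 1) > 1e-9) {
    stop("density must integrate to 1 over the grid (trapezoidal rule)")
  }
  structure(list(values = values, grid = grid), class = "distance_distribution")
}

#' Dipolar evolution trace on a time grid
#'
#' @param values unitless amplitudes, one per time point.
#' @param grid a [time_grid()].
#' @param kind one of `"clean_form_factor"`, `"with_baseline"`, `"noisy"`.
#' @return An object of class `deer_trace`.
#' @export
deer_trace <- function(values, grid,
                       kind = c("clean_form_factor", "with_baseline", "noisy")) {
  stopifnot(inherits(grid, "time_grid"))
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) != grid$n) stop("value count does not match the grid")
  structure(list(values = values, grid = grid, kind = kind),
            class = "deer_trace")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat("Distance distribution on [", x$grid$r_min, ",", x$grid$r_max,
      "] nm, ", x$grid$n, " points\n", sep = "")
  invisible(x)
}

#' @export
print.deer_trace <- function(x, ...) {
  cat("DEER trace (", x$kind, ") on [0, ", x$grid$t_max, "] us, ",
      x$grid$n, " points\n", sep = "")
  invisible(x)
}
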