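# fixtures shared across test files; everything is generated in code

small_grids <- function(n = 64L) {
  list(tgrid = time_grid(3.2, n), dgrid = distance_grid(1.5, 8, n))
}

small_kernel <- function(n = 64L) {
  g <- small_grids(n)
  build_kernel(g$dgrid, g$tgrid)
}

# powder-average quadrature oracle for the dipolar kernel
kernel_quadrature <- function(r, t) {
  if (t == 0) return(1)
  D <- dipolar_coupling(r)
  stats::integrate(function(z) cos((3 * z^2 - 1) * D * t), 0, 1,
                   rel.tol = 1e-11, abs.tol = 1e-12,
                   subdivisions = 2000L)$value
}

random_so <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Qm <- qr.Q(qr(matrix(rnorm(d * d), d)))
  if (det(Qm) < 0) Qm[, 1] <- -Qm[, 1]
  Qm
}

random_net <- function(widths = c(16L, 8L, 16L), seed = 1L,
                       acts = c("sigmoid", "logsig")) {
  layers <- lapply(seq_along(widths[-1]), function(k)
    layer_spec(widths[k + 1], acts[k]))
  init_network(widths[1], layers, seed = seed)
}

# matrix with rows varying smoothly in the row index (low harmonics only)
smooth_row_matrix <- function(d, n_harm = 3L, seed = 1L) {
  set.seed(seed)
  grid <- (0:(d - 1)) / d
  B <- cbind(1, sapply(1:n_harm, function(m) cos(2 * pi * m * grid)),
             sapply(1:n_harm, function(m) sin(2 * pi * m * grid)))
  B %*% matrix(rnorm(ncol(B) * d), ncol(B), d) * 0.5
}

lower_params <- function(Q) Q[lower.tri(Q)]

fd_gradient <- function(p0, problem, h = 1e-6) {
  vapply(seq_along(p0), function(i) {
    e1 <- p0; e1[i] <- e1[i] + h
    e2 <- p0; e2[i] <- e2[i] - h
    (objective_and_gradient(e1, problem)$value -
       objective_and_gradient(e2, problem)$value) / (2 * h)
  }, numeric(1))
}
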