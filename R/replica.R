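# The rational DSP replica of the interpreted network: a zero-frequency
# notch (baseline rejection) and a low-pass (noise rejection), followed by a
# regularized time-distance transform obtained as a Tikhonov pseudoinverse
# with the L-curve choice of lambda.

#' FIR filter specification
#'
#' Normalized frequencies with 1 = Nyquist. For the `highpass_notch` kind the
#' stopband (around zero frequency) ends below the passband edge; for
#' `lowpass` the passband ends below the stopband edge.
#'
#' @param kind `"highpass_notch"` or `"lowpass"`.
#' @param order tap count minus 1; must be even (linear-phase type I).
#' @param passband_edge,stopband_edge band edges in (0, 1).
#' @return list of class `fir_filter_spec`.
#' @export
fir_filter_spec <- function(kind = c("highpass_notch", "lowpass"),
                            order, passband_edge, stopband_edge) {
  kind <- match.arg(kind)
  order <- as.integer(order)
  if (order < 2L || order %% 2L != 0L) {
    stop("order must be even and at least 2 (linear-phase type I design)")
  }
  if (!(passband_edge > 0 && passband_edge < 1) ||
      !(stopband_edge > 0 && stopband_edge < 1)) {
    stop("band edges must lie in (0, 1)")
  }
  if (kind == "highpass_notch" && stopband_edge >= passband_edge) {
    stop("notch: stopband edge must lie below the passband edge")
  }
  if (kind == "lowpass" && passband_edge >= stopband_edge) {
    stop("lowpass: passband edge must lie below the stopband edge")
  }
  structure(list(kind = kind, order = order, passband_edge = passband_edge,
                 stopband_edge = stopband_edge),
            class = "fir_filter_spec")
}

#' Default filter specifications
#'
#' `"full"` scale: the order-256 zero-frequency notch (stopband edge 0.001,
#' passband edge 0.008) and order-32 low-pass (passband edge 0.01, stopband
#' edge 0.3) used for 256-point traces. `"small"` scale: the same roles
#' rescaled for 64-point traces.
#'
#' @param scale `"full"` or `"small"`.
#' @return list with elements `notch` and `lowpass`.
#' @export
default_filter_specs <- function(scale = c("full", "small")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(notch = fir_filter_spec("highpass_notch", 256L, 0.008, 0.001),
         lowpass = fir_filter_spec("lowpass", 32L, 0.01, 0.3))
  } else {
    list(notch = fir_filter_spec("highpass_notch", 56L, 0.065, 0.006),
         lowpass = fir_filter_spec("lowpass", 16L, 0.1, 0.6))
  }
}

# weighted least-squares linear-phase (type I) design; bands is a list of
# c(f_lo, f_hi, amplitude, weight); optional exact zero at DC
firls_design <- function(order, bands, dc_zero = FALSE) {
  M <- order / 2
  G <- matrix(0, M + 1, M + 1)
  bvec <- numeric(M + 1)
  ib <- function(k, w1, w2) if (k == 0) w2 - w1 else (sin(k * w2) - sin(k * w1)) / k
  for (bd in bands) {
    w1 <- bd[1] * pi; w2 <- bd[2] * pi; amp <- bd[3]; wt <- bd[4]
    for (k in 0:M) {
      for (l in k:M) {
        v <- 0.5 * (ib(k + l, w1, w2) + ib(abs(k - l), w1, w2))
        G[k + 1, l + 1] <- G[k + 1, l + 1] + wt * v
        if (l > k) G[l + 1, k + 1] <- G[l + 1, k + 1] + wt * v
      }
      bvec[k + 1] <- bvec[k + 1] + wt * amp * ib(k, w1, w2)
    }
  }
  cc <- if (dc_zero) {
    a <- rep(1, M + 1)                       # A(0) = sum of cosine coefficients
    solve(rbind(cbind(G, a), c(a, 0)), c(bvec, 0))[seq_len(M + 1)]
  } else {
    solve(G, bvec)
  }
  c(rev(cc[-1]) / 2, cc[1], cc[-1] / 2)
}

#' Design a linear-phase FIR filter
#'
#' Weighted least-squares design over the declared bands, with the transition
#' band left unconstrained. The notch kind additionally pins an exact zero at
#' zero frequency (its entire purpose being baseline/DC rejection).
#'
#' @param spec a [fir_filter_spec()].
#' @return An object of class `fir_filter` carrying the `taps` and the spec.
#' @export
design_fir <- function(spec) {
  stopifnot(inherits(spec, "fir_filter_spec"))
  transition <- abs(spec$passband_edge - spec$stopband_edge)
  if (spec$order * transition < 1) {
    stop("filter order too low for the requested transition band")
  }
  taps <- if (spec$kind == "highpass_notch") {
    firls_design(spec$order,
                 list(c(0, spec$stopband_edge, 0, 1),
                      c(spec$passband_edge, 1, 1, 1)),
                 dc_zero = TRUE)
  } else {
    firls_design(spec$order,
                 list(c(0, spec$passband_edge, 1, 1),
                      c(spec$stopband_edge, 1, 0, 1)))
  }
  structure(list(taps = taps, spec = spec), class = "fir_filter")
}

#' @export
print.fir_filter <- function(x, ...) {
  cat("FIR ", x$spec$kind, ": order ", x$spec$order,
      ", passband edge ", x$spec$passband_edge,
      ", stopband edge ", x$spec$stopband_edge, "\n", sep = "")
  invisible(x)
}

#' Frequency response of FIR taps
#'
#' @param filter a `fir_filter` or a numeric tap vector.
#' @param f normalized frequencies (1 = Nyquist).
#' @return complex response values.
#' @export
fir_response <- function(filter, f) {
  taps <- if (inherits(filter, "fir_filter")) filter$taps else as.numeric(filter)
  sapply(f, function(fi) sum(taps * exp(-1i * pi * fi * (seq_along(taps) - 1))))
}

# single linear-phase convolution pass compensating the integer group delay
conv_pass <- function(x, taps) {
  ord <- length(taps) - 1L
  y <- stats::filter(c(x, rep(0, ord)), taps, method = "convolution", sides = 1)
  as.numeric(y[(ord %/% 2 + 1):(ord %/% 2 + length(x))])
}

#' Zero-phase filtering of a trace
#'
#' Forward-backward application of the FIR filter with antisymmetric
#' reflection padding at both ends, so the oscillation phase that the
#' downstream time-distance transform relies on is preserved and the squared
#' magnitude response applies.
#'
#' @param trace a [deer_trace()] or numeric vector.
#' @param filter a `fir_filter` (or tap vector).
#' @return same type as the input, filtered.
#' @export
apply_filter <- function(trace, filter) {
  x <- if (inherits(trace, "deer_trace")) trace$values else as.numeric(trace)
  taps <- if (inherits(filter, "fir_filter")) filter$taps else as.numeric(filter)
  ord <- length(taps) - 1L
  n <- length(x)
  if (n <= ord / 2) stop("trace too short for this filter order")
  pad <- min(n - 1L, ord + 1L)
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- conv_pass(xe, taps)
  y <- rev(conv_pass(rev(y), taps))
  y <- y[(pad + 1):(pad + n)]
  if (inherits(trace, "deer_trace")) deer_trace(y, trace$grid, kind = trace$kind) else y
}

#' Regularized time-distance transform
#'
#' Solves min_T ||T F - targets||_F^2 + lambda ||T||_F^2 in closed form,
#' T = ((F F' + lambda I)^-1 F targets')', where the columns of `F` are
#' (filtered) trace solutions of the forward problem and the columns of
#' `targets` the corresponding distance distributions.
#'
#' @param F n_time x n matrix of trace columns.
#' @param targets n_dist x n matrix of distribution columns.
#' @param lambda regularization parameter, nonnegative.
#' @return An object of class `time_distance_transform` with the matrix
#'   `t_matrix`, `lambda`, and the training matrices.
#' @export
build_transform <- function(F, targets, lambda) {
  if (ncol(F) != ncol(targets)) stop("F and targets must have equal column counts")
  if (lambda < 0) stop("lambda must be nonnegative")
  A <- tcrossprod(F) + lambda * diag(nrow(F))
  sol <- tryCatch(solve(A, F %*% t(targets)),
                  error = function(e) {
                    stop("normal equations are singular; use lambda > 0")
                  })
  structure(list(t_matrix = t(sol), lambda = lambda, F = F, targets = targets),
            class = "time_distance_transform")
}

#' @export
print.time_distance_transform <- function(x, ...) {
  cat("Time-distance transform: ", nrow(x$t_matrix), " x ", ncol(x$t_matrix),
      ", lambda = ", format(x$lambda), ", trained on ", ncol(x$F),
      " pairs\n", sep = "")
  invisible(x)
}

#' L-curve choice of the regularization parameter
#'
#' Computes the residual norm ||T F - targets||_F and solution norm ||T||_F
#' along the lambda grid and returns the lambda at the point of maximum
#' curvature of the (log residual, log solution) curve, both differentiated
#' with respect to log lambda by central differences.
#'
#' @param F,targets as in [build_transform()].
#' @param lambda_grid positive, sorted increasing grid (40 log-spaced points
#'   over 1e-6..1e2 by default).
#' @return the selected lambda, with the L-curve data as attribute `lcurve`.
#' @export
lcurve_lambda <- function(F, targets,
                          lambda_grid = 10^seq(-6, 2, length.out = 40)) {
  if (any(lambda_grid <= 0)) stop("lambda grid must be positive")
  if (is.unsorted(lambda_grid)) stop("lambda grid must be sorted increasing")
  m <- length(lambda_grid)
  if (m < 3L) {
    warning("lambda grid has fewer than 3 points; returning the first")
    return(lambda_grid[1])
  }
  resn <- soln <- numeric(m)
  FFt <- tcrossprod(F)
  FPt <- F %*% t(targets)
  for (i in seq_len(m)) {
    Tm <- t(solve(FFt + lambda_grid[i] * diag(nrow(F)), FPt))
    resn[i] <- norm(Tm %*% F - targets, "F")
    soln[i] <- norm(Tm, "F")
  }
  lx <- log(resn); ly <- log(soln); lt <- log(lambda_grid)
  if (m >= 10L) {
    # parametric curvature of the spline-smoothed curve (raw finite
    # differences are noise-dominated where the curve is flat)
    sx <- stats::smooth.spline(lt, lx, df = min(8, m - 2))
    sy <- stats::smooth.spline(lt, ly, df = min(8, m - 2))
    tt <- seq(min(lt), max(lt), length.out = 10L * m)
    dx <- stats::predict(sx, tt, deriv = 1)$y
    dy <- stats::predict(sy, tt, deriv = 1)$y
    d2x <- stats::predict(sx, tt, deriv = 2)$y
    d2y <- stats::predict(sy, tt, deriv = 2)$y
    curv <- (dx * d2y - dy * d2x) / (dx^2 + dy^2)^1.5
    lam <- lambda_grid[which.min(abs(lt - tt[which.max(curv)]))]
  } else {
    i2 <- 2:(m - 1)
    dx <- (lx[i2 + 1] - lx[i2 - 1]) / (lt[i2 + 1] - lt[i2 - 1])
    dy <- (ly[i2 + 1] - ly[i2 - 1]) / (lt[i2 + 1] - lt[i2 - 1])
    d2x <- (lx[i2 + 1] - 2 * lx[i2] + lx[i2 - 1]) /
      ((lt[i2 + 1] - lt[i2]) * (lt[i2] - lt[i2 - 1]))
    d2y <- (ly[i2 + 1] - 2 * ly[i2] + ly[i2 - 1]) /
      ((lt[i2 + 1] - lt[i2]) * (lt[i2] - lt[i2 - 1]))
    curv <- (dx * d2y - dy * d2x) / (dx^2 + dy^2)^1.5
    lam <- lambda_grid[i2][which.max(curv)]
  }
  attr(lam, "lcurve") <- data.frame(lambda = lambda_grid, residual_norm = resn,
                                    solution_norm = soln)
  lam
}

#' Train the full replica from synthetic data
#'
#' Generates a training set of (distribution, corrupted trace) pairs from the
#' forward model, filters the traces with the notch and low-pass, selects
#' lambda by the L-curve, and builds the time-distance transform on the
#' filtered traces (consistent with the order of stages at prediction time).
#'
#' @param kernel a [build_kernel()] result.
#' @param filters list with `notch` and `lowpass` entries ([design_fir()]
#'   results); defaults chosen by grid size.
#' @param n_pairs number of training pairs.
#' @param config a [synthetic_config()].
#' @param seed master seed.
#' @return list of class `deer_replica` with `filters`, `transform`, `lambda`.
#' @export
train_replica <- function(kernel, filters = NULL, n_pairs = 2000L,
                          config = synthetic_config(), seed = 1L) {
  if (is.null(filters)) {
    scale <- if (kernel$tgrid$n >= 192L) "full" else "small"
    specs <- default_filter_specs(scale)
    filters <- list(notch = design_fir(specs$notch), lowpass = design_fir(specs$lowpass))
  }
  ds <- generate_dataset(n_pairs, kernel, config, seed = seed)
  Ff <- apply(ds$inputs, 2, function(x)
    apply_filter(apply_filter(x, filters$notch), filters$lowpass))
  lam <- lcurve_lambda(Ff, ds$targets)
  tr <- build_transform(Ff, ds$targets, as.numeric(lam))
  structure(list(filters = filters, transform = tr, lambda = as.numeric(lam),
                 dgrid = ds$dgrid, tgrid = ds$tgrid),
            class = "deer_replica")
}

#' @export
print.deer_replica <- function(x, ...) {
  cat("Rational DSP replica: notch + low-pass + regularized time-distance",
      "transform\n")
  print(x$filters$notch); print(x$filters$lowpass); print(x$transform)
  invisible(x)
}

#' Run the replica pipeline on a trace
#'
#' Notch filter (baseline rejection), low-pass filter (noise rejection),
#' time-distance transform, clipping of negative density values, and
#' renormalization to unit integral. An all-zero estimate is returned without
#' renormalization, flagged by attribute `renormalized = FALSE`.
#'
#' @param trace a [deer_trace()] or numeric vector on the replica's time grid.
#' @param replica a [train_replica()] result (or a list with `filters`,
#'   `transform`, `dgrid`).
#' @return A [distance_distribution()] (attribute `renormalized`), or the raw
#'   clipped vector when the estimate is identically zero.
#' @export
replica_pipeline <- function(trace, replica) {
  x <- if (inherits(trace, "deer_trace")) trace$values else as.numeric(trace)
  if (length(x) != ncol(replica$transform$t_matrix)) {
    stop("trace length does not match the transform's time grid")
  }
  y <- apply_filter(apply_filter(x, replica$filters$notch), replica$filters$lowpass)
  est <- as.numeric(replica$transform$t_matrix %*% y)
  est[est < 0] <- 0
  w <- trapezoid_weights(replica$dgrid$r)
  mass <- sum(w * est)
  if (mass <= 0) {
    out <- est
    attr(out, "renormalized") <- FALSE
    return(out)
  }
  out <- distance_distribution(est / mass, replica$dgrid)
  attr(out, "renormalized") <- TRUE
  out
}
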