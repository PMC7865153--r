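# The descrambler-group method: find P in SO(d), parameterized through the
# Cayley transform of an antisymmetric Q, that extremizes an interpretability
# functional of a layer's wiretapped signals. Because the Frobenius objective
# depends on the signals only through their Gram matrix, the input library X
# enters once, in column batches, and each optimizer iteration costs O(d^3).

#' Wiretapped intermediate signals
#'
#' Signals at a chosen tap point of the network: what the layer's activation
#' receives (`before_activation`, the affine output including bias and any
#' stored descrambling transform) or what the next layer receives
#' (`after_activation`).
#'
#' @param net a `fredholm_net`.
#' @param X matrix of input columns.
#' @param layer_index layer to tap.
#' @param tap `"before_activation"` or `"after_activation"`.
#' @return matrix of tapped signal columns.
#' @export
intermediate_signals <- function(net, X, layer_index,
                                 tap = c("before_activation", "after_activation")) {
  tap <- match.arg(tap)
  k <- as.integer(layer_index)
  if (k < 1L || k > length(net$weights)) stop("no such layer")
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  A <- X
  for (j in seq_len(k - 1L)) {
    Z <- net$weights[[j]] %*% A + net$biases[[j]]
    if (!is.null(net$pre_act[[j]])) Z <- net$pre_act[[j]] %*% Z
    A <- activation_fun(Z, net$activations[j])
    if (!is.null(net$post_act[[j]])) A <- net$post_act[[j]] %*% A
  }
  Z <- net$weights[[k]] %*% A + net$biases[[k]]
  if (!is.null(net$pre_act[[k]])) Z <- net$pre_act[[k]] %*% Z
  if (tap == "before_activation") return(Z)
  A <- activation_fun(Z, net$activations[k])
  if (!is.null(net$post_act[[k]])) A <- net$post_act[[k]] %*% A
  A
}

#' Define a descrambling problem
#'
#' Fixes the network, the tap point, the interpretability objective and the
#' input library. Objectives:
#' \describe{
#'   \item{`tikhonov`}{minimize ||D P M||_F^2, the second-derivative norm of
#'     the descrambled tapped signals M (smoothness).}
#'   \item{`tikhonov_plus_link`}{the above plus `link_weight` times
#'     ||W_next P' D||_F^2, the second-derivative norm of the next weight
#'     matrix along its (descrambled) link dimension.}
#'   \item{`max_diag_sum`}{maximize Tr(P W), diagonal dominance of the
#'     descrambled weight matrix (W square).}
#'   \item{`max_diag_normsq`}{maximize ||diag(P W)||_2^2.}
#' }
#'
#' @param net a `fredholm_net`.
#' @param X input library (matrix of columns). May be `NULL` for the pure
#'   weight-matrix objectives.
#' @param layer_index layer to descramble.
#' @param tap tap point, as in [intermediate_signals()].
#' @param objective one of the objectives above.
#' @param link_weight nonnegative weight of the link-smoothness term.
#' @param batch_size optional column batch size for accumulating the signal
#'   Gram matrix.
#' @return A list of class `descrambler_problem`.
#' @export
descrambler_problem <- function(net, X, layer_index = 1L,
                                tap = c("before_activation", "after_activation"),
                                objective = c("tikhonov", "tikhonov_plus_link",
                                              "max_diag_sum", "max_diag_normsq"),
                                link_weight = 1, batch_size = NULL) {
  tap <- match.arg(tap)
  objective <- match.arg(objective)
  if (link_weight < 0) stop("link_weight must be nonnegative")
  k <- as.integer(layer_index)
  if (k < 1L || k > length(net$weights)) stop("no such layer")

  d <- nrow(net$weights[[k]])
  needs_signals <- objective %in% c("tikhonov", "tikhonov_plus_link")
  C <- NULL; n_cols <- 0L
  if (needs_signals) {
    if (is.null(X)) stop("objective '", objective, "' needs an input library X")
    if (is.vector(X)) X <- matrix(X, ncol = 1)
    # Gram matrix of the tapped signals, accumulated over column batches:
    # the Frobenius objective is additive over columns of X.
    bs <- if (is.null(batch_size)) ncol(X) else as.integer(batch_size)
    C <- matrix(0, d, d)
    for (st in seq(1L, ncol(X), bs)) {
      Mb <- intermediate_signals(net, X[, st:min(st + bs - 1L, ncol(X)), drop = FALSE],
                                 k, tap)
      C <- C + tcrossprod(Mb)
    }
    n_cols <- ncol(X)
  }
  W_link <- NULL
  if (objective == "tikhonov_plus_link") {
    if (k >= length(net$weights)) stop("link objective needs a downstream layer")
    W_link <- net$weights[[k + 1L]]
  }
  W_diag <- NULL
  if (objective %in% c("max_diag_sum", "max_diag_normsq")) {
    W_diag <- net$weights[[k]]
    if (nrow(W_diag) != ncol(W_diag)) {
      stop("diagonal-dominance objectives need a square weight matrix")
    }
  }
  structure(list(net = net, layer_index = k, tap = tap, objective = objective,
                 link_weight = link_weight, d = d, C = C, n_cols = n_cols,
                 W_link = W_link, W_diag = W_diag,
                 D2 = if (needs_signals || !is.null(W_link))
                        unclass(spectral_second_derivative(d)) else NULL),
            class = "descrambler_problem")
}

# objective value and gradient with respect to P (d x d, unconstrained)
objective_value_gradP <- function(P, problem) {
  obj <- problem$objective
  if (obj %in% c("tikhonov", "tikhonov_plus_link")) {
    DtD <- crossprod(problem$D2)
    DP <- problem$D2 %*% P
    val <- sum((DP %*% problem$C) * DP)        # Tr(D P C P' D')
    GP <- 2 * DtD %*% P %*% problem$C
    if (obj == "tikhonov_plus_link" && problem$link_weight > 0) {
      A <- crossprod(problem$W_link)           # W'W in the link dimension
      val <- val + problem$link_weight * sum((problem$W_link %*% t(P) %*% problem$D2)^2)
      GP <- GP + problem$link_weight * 2 * DtD %*% P %*% A
    }
    return(list(value = val, gradP = GP))
  }
  if (obj == "max_diag_sum") {
    return(list(value = sum(diag(P %*% problem$W_diag)), gradP = t(problem$W_diag)))
  }
  # max_diag_normsq
  dv <- diag(P %*% problem$W_diag)
  list(value = sum(dv^2), gradP = 2 * dv * t(problem$W_diag))
}

#' Objective and analytic gradient over the antisymmetric generator
#'
#' Evaluates the selected functional at P = cayley(Q) together with its exact
#' gradient with respect to Q, obtained by the chain rule through the Cayley
#' map, dP = -(1 + P) dQ (1 + Q)^-1, and projection onto the antisymmetric
#' subspace.
#'
#' @param q antisymmetric matrix or strict-lower-triangle parameter vector.
#' @param problem a [descrambler_problem()].
#' @return list with `value` (scalar) and `gradient` (antisymmetric d x d
#'   matrix; entry (i, j), i > j, is the derivative in the (i, j) parameter
#'   up to the factor 2 absorbed by antisymmetry).
#' @export
objective_and_gradient <- function(q, problem) {
  d <- problem$d
  Q <- antisymmetric(q, d)
  Id <- diag(d)
  Binv <- solve(Id + Q)
  P <- (Id - Q) %*% Binv
  vg <- objective_value_gradP(P, problem)
  # d eta = Tr(G' dP), dP = -(1 + P) dQ (1 + Q)^-1  =>
  # unconstrained dQ-gradient E = -(1 + P)' G (1 + Q)^-T = -(1 + P)' G (1 - Q)^-1
  E <- -crossprod(Id + P, vg$gradP) %*% solve(Id - Q)
  list(value = vg$value, gradient = (E - t(E)) / 2)
}

#' Descrambler optimizer control
#'
#' @param maxiter iteration cap of the quasi-Newton optimizer.
#' @param tol stop when the gradient infinity-norm falls below this.
#' @param memory number of L-BFGS correction pairs.
#' @return list of class `descramble_control`.
#' @export
descramble_control <- function(maxiter = 500L, tol = 1e-8, memory = 10L) {
  structure(list(maxiter = as.integer(maxiter), tol = tol,
                 memory = as.integer(memory)),
            class = "descramble_control")
}

#' Fit a descrambling transformation
#'
#' Limited-memory BFGS over the strictly-lower-triangular parameters of the
#' antisymmetric generator, started at Q = 0 (P = identity). The two
#' diagonal-dominance objectives are maximized (by negation); the smoothness
#' objectives are minimized. Non-convergence within the iteration cap is
#' reported through the `converged` flag, not an error.
#'
#' @param problem a [descrambler_problem()].
#' @param control a [descramble_control()].
#' @return An object of class `descrambler_fit`: `q_star` (antisymmetric
#'   generator), `p_star` (in SO(d)), `objective_history` (best value so far
#'   at each function evaluation), `value`, `value0` (at P = identity),
#'   `gradient_norm`, `converged`, `counts`, and the problem metadata.
#' @export
descramble <- function(problem, control = descramble_control()) {
  stopifnot(inherits(problem, "descrambler_problem"))
  d <- problem$d
  maximize <- problem$objective %in% c("max_diag_sum", "max_diag_normsq")
  sgn <- if (maximize) -1 else 1
  history <- new.env(parent = emptyenv())
  history$values <- numeric(0)

  fn <- function(p) {
    v <- objective_and_gradient(p, problem)$value
    best <- if (length(history$values)) {
      if (maximize) max(history$values[length(history$values)], v)
      else min(history$values[length(history$values)], v)
    } else v
    history$values <- c(history$values, best)
    sgn * v
  }
  gr <- function(p) {
    g <- objective_and_gradient(p, problem)$gradient
    sgn * 2 * antisymmetric_params(g)  # d/dq_ij = E_ij - E_ji = 2 * gradient_ij
  }

  p0 <- rep(0, d * (d - 1) / 2)
  opt <- stats::optim(p0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = control$maxiter,
                                     lmm = control$memory,
                                     factr = 10, pgtol = control$tol / 2))
  q_star <- antisymmetric(opt$par, d)
  p_star <- cayley(q_star)
  gnorm <- max(abs(gr(opt$par)))
  structure(list(q_star = q_star, p_star = p_star,
                 objective_history = history$values,
                 value = sgn * opt$value,
                 value0 = objective_and_gradient(p0 * 0, problem)$value,
                 gradient_norm = gnorm,
                 converged = (gnorm <= control$tol) || opt$convergence == 0L,
                 counts = opt$counts, optim_message = opt$message,
                 objective = problem$objective, layer_index = problem$layer_index,
                 tap = problem$tap, d = d),
            class = "descrambler_fit")
}

#' @export
print.descrambler_fit <- function(x, ...) {
  cat("Descrambler fit (", x$objective, "), layer ", x$layer_index,
      ", tap ", x$tap, ", d = ", x$d, "\n", sep = "")
  cat("objective: ", format(x$value0), " -> ", format(x$value),
      if (x$converged) "  (converged)\n" else "  (iteration cap reached)\n",
      sep = "")
  invisible(x)
}

#' @export
summary.descrambler_fit <- function(object, ...) {
  orth <- norm(object$p_star %*% t(object$p_star) - diag(object$d), "F")
  out <- list(objective = object$objective, d = object$d,
              value0 = object$value0, value = object$value,
              reduction = if (object$value != 0) object$value0 / object$value else Inf,
              gradient_norm = object$gradient_norm,
              orthogonality_error = orth, det = det(object$p_star),
              evaluations = object$counts, converged = object$converged)
  class(out) <- "summary.descrambler_fit"
  out
}

#' @export
print.summary.descrambler_fit <- function(x, ...) {
  cat("Descrambler fit summary\n")
  cat("  objective      :", x$objective, "(d =", x$d, ")\n")
  cat("  value          :", format(x$value0), "->", format(x$value), "\n")
  cat("  factor         :", format(x$reduction), "\n")
  cat("  |grad|_inf     :", format(x$gradient_norm), "\n")
  cat("  ||PP' - I||_F  :", format(x$orthogonality_error), "\n")
  cat("  det(P)         :", format(x$det), "\n")
  cat("  converged      :", x$converged, "\n")
  invisible(x)
}

#' @export
coef.descrambler_fit <- function(object, ...) object$p_star

#' @export
plot.descrambler_fit <- function(x, ...) {
  graphics::plot(seq_along(x$objective_history), x$objective_history,
                 type = "l", log = "y", xlab = "function evaluation",
                 ylab = "best objective so far",
                 main = paste("descrambling:", x$objective), ...)
  invisible(x)
}

#' Diagonal-dominance objectives
#'
#' Values of the two weight-matrix functionals at P = cayley(q):
#' `max_diag_sum` gives Tr(P W), `max_diag_normsq` gives ||diag(P W)||_2^2.
#'
#' @param q antisymmetric matrix or parameter vector.
#' @param W square weight matrix in the descrambled dimension.
#' @param mode which functional.
#' @return scalar.
#' @export
diagonal_objectives <- function(q, W, mode = c("max_diag_sum", "max_diag_normsq")) {
  mode <- match.arg(mode)
  if (nrow(W) != ncol(W)) stop("diagonal objectives need a square matrix")
  P <- cayley(q, nrow(W))
  dv <- diag(P %*% W)
  if (mode == "max_diag_sum") sum(dv) else sum(dv^2)
}

#' Absorb a descrambler into the network
#'
#' Rewrites the network in the descrambled representation without changing
#' its function. For the `before_activation` tap, W_k and its bias are
#' rotated by P and the inverse is stored as an orthogonal undo applied
#' between the affine map and the activation (the nonlinearity blocks
#' absorption into the next weight matrix). For the `after_activation` tap,
#' P is stored after the activation and P' is absorbed into W_(k+1) (or kept
#' as an output-side undo on the last layer).
#'
#' @param net a `fredholm_net`.
#' @param layer_index layer at whose tap P acts.
#' @param tap tap point.
#' @param P orthogonal matrix in the tapped dimension.
#' @return The rewritten, functionally identical network.
#' @export
apply_descrambler <- function(net, layer_index,
                              tap = c("before_activation", "after_activation"), P) {
  tap <- match.arg(tap)
  k <- as.integer(layer_index)
  if (k < 1L || k > length(net$weights)) stop("no such layer")
  d <- nrow(net$weights[[k]])
  if (!is.matrix(P) || any(dim(P) != d)) stop("P must be square in the tapped dimension")
  if (norm(P %*% t(P) - diag(d), "F") > 1e-6) stop("P is not orthogonal")

  if (tap == "before_activation") {
    net$weights[[k]] <- P %*% net$weights[[k]]
    net$biases[[k]] <- as.numeric(P %*% net$biases[[k]])
    undo <- if (is.null(net$pre_act[[k]])) t(P) else net$pre_act[[k]] %*% t(P)
    # drop the undo once it collapses back to the identity
    net$pre_act[k] <- if (norm(undo - diag(d), "F") < 1e-12) list(NULL) else list(undo)
  } else {
    post <- if (is.null(net$post_act[[k]])) P else P %*% net$post_act[[k]]
    net$post_act[k] <- if (norm(post - diag(d), "F") < 1e-12) list(NULL) else list(post)
    if (k < length(net$weights)) {
      net$weights[[k + 1L]] <- net$weights[[k + 1L]] %*% t(P)
    } else {
      # last layer: record the output-side undo
      net$output_undo <- if (is.null(net$output_undo)) t(P) else net$output_undo %*% t(P)
    }
  }
  net
}
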