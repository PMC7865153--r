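# Small fully connected feed-forward networks, y = F_n W_n ... F_1 W_1 x,
# trained to invert the discretized Fredholm transform. Plain-array
# implementation: forward pass, reverse-mode gradients, Adam updates.

activation_fun <- function(z, tag) {
  switch(tag,
    tanh     = tanh(z),
    logsig   = 1 / (1 + exp(-z)),
    identity = z,
    stop("unknown activation tag: ", tag)
  )
}

# derivative expressed through the activation output (cheap for both sigmoids)
activation_deriv <- function(a, tag) {
  switch(tag,
    tanh     = 1 - a^2,
    logsig   = a * (1 - a),
    identity = 1,
    stop("unknown activation tag: ", tag)
  )
}

#' Layer specification
#'
#' @param output_width positive perceptron count.
#' @param activation one of `"sigmoid"` (tanh), `"logsig"` (logistic),
#'   `"identity"`. The hidden "sigmoidal" activation is tanh and the output
#'   "logsig" is the logistic function, whose positive range suits outputs
#'   with the meaning of a probability density.
#' @return A list of class `layer_spec`.
#' @export
layer_spec <- function(output_width, activation = c("sigmoid", "logsig", "identity")) {
  activation <- match.arg(activation)
  output_width <- as.integer(output_width)
  if (output_width < 1L) stop("output width must be positive")
  tag <- if (activation == "sigmoid") "tanh" else activation
  structure(list(output_width = output_width, activation = tag),
            class = "layer_spec")
}

#' Initialize a fully connected network
#'
#' Glorot-uniform weights and zero biases, reproducible from the seed.
#'
#' @param input_width input dimension.
#' @param layers list of [layer_spec()] in order.
#' @param seed integer seed.
#' @return An object of class `fredholm_net` with fields `weights`, `biases`,
#'   `activations`, and optional per-layer orthogonal `pre_act` / `post_act`
#'   transforms inserted by [apply_descrambler()].
#' @export
init_network <- function(input_width, layers, seed = 1L) {
  set.seed(seed)
  widths <- c(as.integer(input_width), vapply(layers, `[[`, 1L, "output_width"))
  nl <- length(layers)
  weights <- biases <- vector("list", nl)
  for (k in seq_len(nl)) {
    lim <- sqrt(6 / (widths[k] + widths[k + 1]))
    weights[[k]] <- matrix(stats::runif(widths[k + 1] * widths[k], -lim, lim),
                           widths[k + 1], widths[k])
    biases[[k]] <- rep(0, widths[k + 1])
  }
  structure(list(weights = weights, biases = biases,
                 activations = vapply(layers, `[[`, "", "activation"),
                 pre_act = vector("list", nl), post_act = vector("list", nl),
                 input_width = as.integer(input_width),
                 target_scale = 1, loss_history = numeric(0)),
            class = "fredholm_net")
}

validate_net <- function(net) {
  nl <- length(net$weights)
  stopifnot(length(net$biases) == nl, length(net$activations) == nl)
  din <- net$input_width
  for (k in seq_len(nl)) {
    if (ncol(net$weights[[k]]) != din) stop("weight matrices do not chain")
    if (length(net$biases[[k]]) != nrow(net$weights[[k]])) {
      stop("bias length must equal layer output width")
    }
    din <- nrow(net$weights[[k]])
  }
  invisible(net)
}

#' Forward pass
#'
#' Applies each affine map, any stored orthogonal descrambling transforms,
#' and the layer activation, in order. Columns of `X` are independent inputs.
#'
#' @param net a `fredholm_net`.
#' @param X numeric matrix of input columns (a vector is taken as one column).
#' @return matrix of output columns.
#' @export
network_forward <- function(net, X) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (nrow(X) != net$input_width) stop("input row count does not match the network")
  A <- X
  for (k in seq_along(net$weights)) {
    Z <- net$weights[[k]] %*% A + net$biases[[k]]
    if (!is.null(net$pre_act[[k]])) Z <- net$pre_act[[k]] %*% Z
    A <- activation_fun(Z, net$activations[k])
    if (!is.null(net$post_act[[k]])) A <- net$post_act[[k]] %*% A
  }
  if (!is.null(net$output_undo)) A <- net$output_undo %*% A
  A
}

#' @export
print.fredholm_net <- function(x, ...) {
  widths <- c(x$input_width, vapply(x$weights, nrow, 1L))
  cat("Fredholm solver network: ", paste(widths, collapse = " -> "),
      " (", paste(x$activations, collapse = ", "), ")\n", sep = "")
  if (length(x$loss_history)) {
    cat("trained, final loss ", format(utils::tail(x$loss_history, 1)), "\n", sep = "")
  }
  invisible(x)
}

#' Predict distance distributions from traces
#'
#' @param object a trained `fredholm_net`.
#' @param newdata matrix of trace columns, or a [deer_trace()].
#' @param ... unused.
#' @return matrix of network outputs divided by the stored target scale
#'   (densities per nm when trained through [train_network()]).
#' @export
predict.fredholm_net <- function(object, newdata, ...) {
  if (inherits(newdata, "deer_trace")) newdata <- matrix(newdata$values, ncol = 1)
  network_forward(object, newdata) / object$target_scale
}

#' Training configuration
#'
#' @param epochs passes over the data, at least 1.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param val_fraction fraction of records held out for validation, in \[0, 1).
#' @param seed integer seed controlling shuffling (and nothing else).
#' @param loss only `"mse"` is implemented.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 600L, batch_size = 100L, learning_rate = 2e-3,
                         val_fraction = 0.1, seed = 1L, loss = "mse") {
  if (epochs < 1L) stop("epochs must be at least 1")
  if (val_fraction < 0 || val_fraction >= 1) stop("val_fraction must be in [0, 1)")
  if (loss != "mse") stop("only mean squared error loss is implemented")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, val_fraction = val_fraction,
                 seed = as.integer(seed), loss = loss),
            class = "train_config")
}

#' Train a network with Adam
#'
#' Minimizes the mean squared error between network outputs and targets.
#' When `data` is a [generate_dataset()] result, targets are the distance
#' densities multiplied by the grid step (per-bin probability mass), which
#' keeps them inside the logistic output range; the scale is stored on the
#' network and undone by [predict.fredholm_net()]. Training is a pure
#' function of the initial network and the config seed.
#'
#' @param net an [init_network()] result.
#' @param data a `deer_dataset`, or a list with matrices `X` and `Y`.
#' @param config a [train_config()].
#' @return The trained network; `loss_history` holds per-epoch training MSE,
#'   attribute `val_nrmse` the validation normalized RMSE (if held out).
#' @export
train_network <- function(net, data, config = train_config()) {
  validate_net(net)
  if (inherits(data, "deer_dataset")) {
    X <- data$inputs
    scale <- data$dgrid$r[2] - data$dgrid$r[1]
    Y <- data$targets * scale
    net$target_scale <- scale
  } else {
    X <- data$X; Y <- data$Y
    net$target_scale <- 1
  }
  if (ncol(X) != ncol(Y)) stop("inputs and targets must pair up column-wise")
  if (nrow(X) != net$input_width) stop("dataset dimensions do not match the network")

  set.seed(config$seed)
  n <- ncol(X)
  n_val <- floor(config$val_fraction * n)
  idx <- sample(n)
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx, val_idx)
  Xtr <- X[, tr_idx, drop = FALSE]; Ytr <- Y[, tr_idx, drop = FALSE]

  nl <- length(net$weights)
  mW <- lapply(net$weights, function(w) w * 0); vW <- mW
  mb <- lapply(net$biases, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  it <- 0L
  ntr <- ncol(Xtr)
  hist <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample(ntr)
    tot <- 0
    for (st in seq(1L, ntr, config$batch_size)) {
      bi <- ord[st:min(st + config$batch_size - 1L, ntr)]
      A <- vector("list", nl + 1L)
      A[[1]] <- Xtr[, bi, drop = FALSE]
      for (k in seq_len(nl)) {
        A[[k + 1]] <- activation_fun(net$weights[[k]] %*% A[[k]] + net$biases[[k]],
                                     net$activations[k])
      }
      err <- A[[nl + 1]] - Ytr[, bi, drop = FALSE]
      tot <- tot + sum(err^2)
      delta <- 2 * err / (length(bi) * nrow(err))
      it <- it + 1L
      c1 <- 1 - b1^it; c2 <- 1 - b2^it
      for (k in nl:1) {
        delta <- delta * activation_deriv(A[[k + 1]], net$activations[k])
        gW <- tcrossprod(delta, A[[k]])
        gb <- rowSums(delta)
        if (k > 1L) delta <- crossprod(net$weights[[k]], delta)
        mW[[k]] <- b1 * mW[[k]] + (1 - b1) * gW
        vW[[k]] <- b2 * vW[[k]] + (1 - b2) * gW^2
        mb[[k]] <- b1 * mb[[k]] + (1 - b1) * gb
        vb[[k]] <- b2 * vb[[k]] + (1 - b2) * gb^2
        net$weights[[k]] <- net$weights[[k]] - lr * (mW[[k]] / c1) / (sqrt(vW[[k]] / c2) + eps)
        net$biases[[k]]  <- net$biases[[k]]  - lr * (mb[[k]] / c1) / (sqrt(vb[[k]] / c2) + eps)
      }
    }
    hist[ep] <- tot / (ntr * nrow(Y))
    if (!is.finite(hist[ep])) {
      stop("training diverged (non-finite loss) at epoch ", ep,
           "; try a smaller learning rate")
    }
  }
  net$loss_history <- hist
  if (length(val_idx)) {
    Yv <- Y[, val_idx, drop = FALSE]
    pred <- network_forward(net, X[, val_idx, drop = FALSE])
    attr(net, "val_nrmse") <- sqrt(mean((pred - Yv)^2)) / stats::sd(Yv)
  }
  net
}

#' Train an ensemble of independently initialized networks
#'
#' @param input_width,layers network architecture as in [init_network()].
#' @param data,config as in [train_network()]; member seeds (initialization
#'   and shuffling) derive deterministically from `config$seed`.
#' @param n_nets ensemble size, at least 1.
#' @return list of trained `fredholm_net` objects.
#' @export
ensemble_train <- function(input_width, layers, data, config = train_config(),
                           n_nets = 5L) {
  n_nets <- as.integer(n_nets)
  if (n_nets < 1L) stop("n_nets must be at least 1")
  lapply(seq_len(n_nets), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 7000L + i)
    net <- init_network(input_width, layers, seed = derive_seed(config$seed, 9000L + i))
    tryCatch(train_network(net, data, cfg),
             error = function(e) stop("ensemble member ", i, ": ", conditionMessage(e)))
  })
}

#' Ensemble statistics for one input trace
#'
#' @param nets list of trained networks (at least 2 for meaningful bands).
#' @param trace a [deer_trace()] or numeric vector.
#' @param probs lower/upper quantile levels of the spread band.
#' @return list with `mean`, `lower`, `upper` (pointwise across members) and
#'   the member output matrix `members`.
#' @export
ensemble_stats <- function(nets, trace, probs = c(0.05, 0.95)) {
  if (length(nets) < 2L) warning("single-member ensemble: spread bands are degenerate")
  x <- if (inherits(trace, "deer_trace")) trace$values else as.numeric(trace)
  outs <- vapply(nets, function(nn) as.numeric(predict(nn, matrix(x, ncol = 1))),
                 numeric(nrow(nets[[1]]$weights[[length(nets[[1]]$weights)]])))
  outs <- matrix(outs, ncol = length(nets))
  list(mean = rowMeans(outs),
       lower = apply(outs, 1, stats::quantile, probs = probs[1]),
       upper = apply(outs, 1, stats::quantile, probs = probs[2]),
       members = outs)
}

#' Reduce the link dimension of a fully connected layer
#'
#' Splits layer `layer_index` through the SVD of its weight matrix
#' W = U S V': the layer becomes an identity-activation factor
#' sqrt(S_r) V_r' feeding U_r sqrt(S_r) (which keeps the original bias and
#' activation), so the link between the two factors is an explicit
#' r-dimensional bottleneck. At full rank the product reassembles W exactly;
#' in general the pre-activation perturbation is bounded by the discarded
#' singular values.
#'
#' @param net a `fredholm_net`.
#' @param layer_index layer whose weight matrix is factorized.
#' @param rank target link dimension, or `NULL` to use `tol`.
#' @param tol drop singular values below `tol * s_max` (default 1e-8).
#' @return The restructured network (one extra layer); attribute
#'   `dropped_singular_values` records what was discarded.
#' @export
rank_truncate <- function(net, layer_index, rank = NULL, tol = NULL) {
  validate_net(net)
  k <- as.integer(layer_index)
  if (k < 1L || k > length(net$weights)) stop("no such layer")
  if (!is.null(net$pre_act[[k]]) || !is.null(net$post_act[[k]])) {
    stop("cannot truncate a layer carrying descrambling transforms")
  }
  W <- net$weights[[k]]
  sv <- svd(W)
  d <- length(sv$d)
  if (is.null(rank)) {
    if (is.null(tol)) tol <- 1e-8
    rank <- max(1L, sum(sv$d > tol * sv$d[1]))
  }
  rank <- as.integer(rank)
  if (rank < 1L || rank > d) stop("rank must lie in 1..min(dim(W))")
  rs <- sqrt(sv$d[seq_len(rank)])
  W_in  <- rs * t(sv$v[, seq_len(rank), drop = FALSE])   # r x n_in
  W_out <- sv$u[, seq_len(rank), drop = FALSE] %*% diag(rs, rank)  # n_out x r

  net$weights <- append(net$weights[-k], list(W_in, W_out), after = k - 1L)
  net$biases  <- append(net$biases[-k], list(rep(0, rank), net$biases[[k]]),
                        after = k - 1L)
  net$activations <- append(net$activations[-k],
                            c("identity", net$activations[k]), after = k - 1L)
  net$pre_act  <- append(net$pre_act[-k], list(NULL, NULL), after = k - 1L)
  net$post_act <- append(net$post_act[-k], list(NULL, NULL), after = k - 1L)
  attr(net, "dropped_singular_values") <- if (rank < d) sv$d[(rank + 1):d] else numeric(0)
  net
}

#' Full-scale architecture defaults
#'
#' The two-fully-connected-layer layout: 256-point input and output with a
#' tanh hidden layer and a logistic output layer, and link dimension reducible
#' to 80 by discarding insignificant singular values.
#'
#' @return list with `input_width`, `layers`, `link_rank`, and default grids.
#' @export
full_scale_config <- function() {
  list(input_width = 256L,
       layers = list(layer_spec(256L, "sigmoid"), layer_spec(256L, "logsig")),
       link_rank = 80L,
       tgrid = time_grid(3.2, 256L),
       dgrid = distance_grid(1.5, 8, 256L))
}
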