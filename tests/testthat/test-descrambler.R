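test_that("Cayley transform maps antisymmetric generators into SO(d)", {
  expect_equal(cayley(rep(0, 6), 4), diag(4))

  # 2x2, Q[1,2] = 1: direct arithmetic oracle gives the quarter-turn rotation
  Q2 <- matrix(c(0, -1, 1, 0), 2)  # column-major: Q[1,2] = 1
  oracle <- (diag(2) - Q2) %*% solve(diag(2) + Q2)
  expect_equal(cayley(Q2), matrix(c(0, 1, -1, 0), 2))  # [[0,-1],[1,0]]
  expect_equal(cayley(Q2), oracle, tolerance = 1e-15)

  set.seed(4)
  for (rep in 1:5) {
    P <- cayley(rnorm(16 * 15 / 2), 16)
    expect_lt(norm(P %*% t(P) - diag(16), "F"), 1e-12)
    expect_equal(det(P), 1, tolerance = 1e-10)
  }
})

test_that("Cayley inverse and operator-order identities hold", {
  set.seed(8)
  p <- rnorm(28)
  Q <- antisymmetric(p, 8)
  P <- cayley(Q)
  expect_equal(cayley(-Q), t(P), tolerance = 1e-12)
  expect_equal(t(P) %*% P, diag(8), tolerance = 1e-12)
  # both operator orders agree (rational functions of Q commute)
  other <- solve(diag(8) + Q) %*% (diag(8) - Q)
  expect_equal(P, other, tolerance = 1e-12)
})

test_that("spectral second derivative annihilates constants and scales harmonics", {
  D2 <- spectral_second_derivative(32)
  expect_lt(max(abs(unclass(D2) %*% rep(1, 32))), 1e-10)
  expect_lt(max(abs(rowSums(unclass(D2)))), 1e-10)
  j <- 0:31
  v <- cos(2 * pi * j / 32)
  expect_equal(as.numeric(unclass(D2) %*% v), -(2 * pi)^2 * v, tolerance = 1e-8)
  expect_equal(unclass(D2), t(unclass(D2)), tolerance = 1e-10)
  expect_error(spectral_second_derivative(31), "even")
})

test_that("the Tikhonov functional is the column-additive second-derivative norm", {
  D2 <- spectral_second_derivative(16)
  expect_equal(tikhonov_norm(matrix(3, 16, 4), D2), 0, tolerance = 1e-12)
  set.seed(5)
  v1 <- rnorm(16); v2 <- rnorm(16)
  expect_equal(tikhonov_norm(cbind(v1, v2), D2),
               tikhonov_norm(v1, D2) + tikhonov_norm(v2, D2), tolerance = 1e-10)
  # single harmonic of frequency index m: closed-form eigenvalue (2 pi m)^4
  m <- 3
  v <- sin(2 * pi * m * (0:15) / 16)
  expect_equal(tikhonov_norm(v, D2), (2 * pi * m)^4 * sum(v^2),
               tolerance = 1e-6 * (2 * pi * m)^4 * sum(v^2))
})

test_that("intermediate signals match the truncated forward pass", {
  net <- random_net(c(10L, 6L, 10L), seed = 2)
  X <- matrix(rnorm(10 * 7), 10)
  pre <- intermediate_signals(net, X, 1L, "before_activation")
  expect_equal(pre, net$weights[[1]] %*% X + net$biases[[1]])
  post <- intermediate_signals(net, X, 1L, "after_activation")
  expect_equal(post, tanh(pre))
  # independent re-evaluation oracle at layer 2
  pre2 <- intermediate_signals(net, X, 2L, "before_activation")
  expect_equal(pre2, net$weights[[2]] %*% tanh(net$weights[[1]] %*% X +
                                                 net$biases[[1]]) + net$biases[[2]],
               tolerance = 1e-12)
})

test_that("objective value and analytic gradient are exact", {
  net <- random_net(c(16L, 8L, 16L), seed = 6)
  k <- small_kernel(16L)
  ds <- generate_dataset(12, k, seed = 3)
  prob <- descrambler_problem(net, ds$inputs, 1L, "before_activation", "tikhonov")

  # X = 0: objective and gradient vanish
  prob0 <- descrambler_problem(net, matrix(0, 16, 4) , 1L, "before_activation", "tikhonov")
  # bias still contributes; zero out biases to test the stated limit
  net0 <- net; net0$biases[[1]] <- rep(0, 8)
  prob0 <- descrambler_problem(net0, matrix(0, 16, 4), 1L, "before_activation", "tikhonov")
  og0 <- objective_and_gradient(rep(0.1, 28), prob0)
  expect_equal(og0$value, 0)
  expect_equal(og0$gradient, matrix(0, 8, 8))

  # q = 0: objective equals the raw Tikhonov norm of the tapped signals
  M <- intermediate_signals(net, ds$inputs, 1L, "before_activation")
  D2 <- spectral_second_derivative(8)
  expect_equal(objective_and_gradient(rep(0, 28), prob)$value,
               tikhonov_norm(M, D2), tolerance = 1e-10)

  # finite differences across all objective modes
  set.seed(9)
  for (obj in c("tikhonov", "tikhonov_plus_link")) {
    pr <- descrambler_problem(net, ds$inputs, 1L, "before_activation", obj,
                              link_weight = 0.7)
    p0 <- rnorm(28) * 0.2
    g <- 2 * lower_params(objective_and_gradient(p0, pr)$gradient)
    fd <- fd_gradient(p0, pr)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-6)
  }
})

test_that("batched Gram accumulation equals whole-array evaluation", {
  net <- random_net(c(16L, 8L, 16L), seed = 10)
  X <- matrix(rnorm(16 * 50), 16)
  pa <- descrambler_problem(net, X, 1L, "before_activation", "tikhonov")
  pb <- descrambler_problem(net, X, 1L, "before_activation", "tikhonov",
                            batch_size = 7L)
  expect_equal(pa$C, pb$C, tolerance = 1e-10)
  p0 <- rnorm(28) * 0.1
  expect_equal(objective_and_gradient(p0, pa)$value,
               objective_and_gradient(p0, pb)$value, tolerance = 1e-10)
})

test_that("descrambling a zero-signal problem stays at the identity", {
  net <- random_net(c(8L, 4L, 8L), seed = 1)
  net$biases[[1]] <- rep(0, 4)
  prob <- descrambler_problem(net, matrix(0, 8, 5), 1L, "before_activation", "tikhonov")
  fit <- descramble(prob, descramble_control(maxiter = 50))
  expect_equal(fit$p_star, diag(4))
  expect_true(fit$converged)
})

test_that("planted scrambling is recovered with spectrum preserved", {
  d <- 16L
  for (s in 1:3) {
    W_s <- smooth_row_matrix(d, seed = 40 + s)
    R <- random_so(d, seed = 50 + s)
    set.seed(60 + s)
    X <- matrix(rnorm(d * 128), d)
    M <- t(R) %*% W_s %*% X
    net <- init_network(d, list(layer_spec(d, "identity")), seed = 1)
    net$weights[[1]] <- t(R) %*% W_s
    prob <- descrambler_problem(net, X, 1L, "before_activation", "tikhonov")
    fit <- descramble(prob, descramble_control(maxiter = 1500))
    D2 <- spectral_second_derivative(d)
    planted <- tikhonov_norm(R %*% M, D2)
    expect_lte(fit$value, 1.05 * planted)
    # objective history is monotone non-increasing
    expect_true(all(diff(fit$objective_history) <= 1e-9))
    # orthogonal descrambling preserves singular values
    expect_equal(svd(fit$p_star %*% net$weights[[1]])$d, svd(net$weights[[1]])$d,
                 tolerance = 1e-10)
  }
})

test_that("diagonal-dominance objectives behave per their closed forms", {
  expect_equal(diagonal_objectives(rep(0, 28), diag(8), "max_diag_sum"), 8)
  set.seed(3)
  W <- matrix(rnorm(36), 6)
  sv <- svd(W)$d
  for (rep in 1:10) {
    P <- random_so(6)
    expect_lte(sum(diag(P %*% W)), sum(sv) + 1e-10)  # von Neumann
  }
  # planted SO(2) rotation: angle-grid oracle finds the same optimum
  th0 <- 1.1
  W2 <- matrix(c(cos(th0), -sin(th0), sin(th0), cos(th0)), 2)  # R(th0)
  net <- init_network(2L, list(layer_spec(2L, "identity")), seed = 1)
  net$weights[[1]] <- W2
  prob <- descrambler_problem(net, NULL, 1L, "before_activation", "max_diag_sum")
  fit <- descramble(prob, descramble_control(maxiter = 200))
  th_grid <- seq(-pi, pi, length.out = 100000)
  oracle <- max(vapply(th_grid, function(th) {
    sum(diag(matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2) %*% W2))
  }, 1))
  expect_equal(fit$value, oracle, tolerance = 1e-6)
  expect_equal(fit$value, 2, tolerance = 1e-6)
  expect_equal(fit$p_star, t(W2), tolerance = 1e-4)
})

test_that("absorbing the descrambler never changes the network function", {
  set.seed(12)
  for (s in 1:5) {
    net <- random_net(c(12L, 8L, 12L), seed = 70 + s)
    X <- matrix(rnorm(12 * 9), 12)
    y0 <- network_forward(net, X)
    P <- random_so(8)
    pre <- apply_descrambler(net, 1L, "before_activation", P)
    post <- apply_descrambler(net, 1L, "after_activation", P)
    expect_lt(max(abs(network_forward(pre, X) - y0)) / max(abs(y0)), 1e-8)
    expect_lt(max(abs(network_forward(post, X) - y0)) / max(abs(y0)), 1e-8)
    # group inverse restores the original weights
    back <- apply_descrambler(pre, 1L, "before_activation", t(P))
    expect_equal(back$weights[[1]], net$weights[[1]], tolerance = 1e-10)
    expect_null(back$pre_act[[1]])
  }
  net <- random_net(c(6L, 4L, 6L), seed = 1)
  expect_equal(apply_descrambler(net, 1L, "before_activation", diag(4))$weights,
               net$weights)
  expect_error(apply_descrambler(net, 1L, "before_activation",
                                 diag(4) + 0.1), "orthogonal")
})

test_that("descrambler fit object exposes the standard accessor surface", {
  net <- random_net(c(8L, 4L, 8L), seed = 3)
  X <- matrix(rnorm(8 * 20), 8)
  fit <- descramble(descrambler_problem(net, X, 1L, "before_activation", "tikhonov"),
                    descramble_control(maxiter = 300))
  expect_s3_class(fit, "descrambler_fit")
  expect_equal(coef(fit), fit$p_star)
  s <- summary(fit)
  expect_lt(s$orthogonality_error, 1e-8)
  expect_equal(s$det, 1, tolerance = 1e-6)
  expect_output(print(fit), "Descrambler fit")
})
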