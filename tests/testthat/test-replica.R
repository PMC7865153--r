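test_that("FIR specs validate their band geometry", {
  expect_error(fir_filter_spec("highpass_notch", 57, 0.01, 0.001), "even")
  expect_error(fir_filter_spec("highpass_notch", 56, 0.001, 0.008), "below")
  expect_error(fir_filter_spec("lowpass", 32, 0.3, 0.01), "below")
  expect_error(fir_filter_spec("lowpass", 32, 0, 0.3), "edges")
  expect_error(design_fir(fir_filter_spec("lowpass", 4, 0.1, 0.15)),
               "order too low")
})

test_that("the default notch rejects DC and passes the band", {
  f <- design_fir(default_filter_specs("full")$notch)
  expect_length(f$taps, 257L)
  expect_lt(abs(sum(f$taps)), 1e-3)            # |H(0)|: DC is rejected
  fr <- seq(0.012, 1, length.out = 400)        # beyond the transition edge
  H <- abs(fir_response(f, fr))
  expect_lt(max(abs(20 * log10(H))), 1)        # < 1 dB away from the edge
  # the response at the nominal passband edge has recovered to within 3 dB
  expect_gt(abs(fir_response(f, 0.008)), 10^(-3 / 20))
})

test_that("the default low-pass is flat in band and attenuates the stopband", {
  f <- design_fir(default_filter_specs("full")$lowpass)
  expect_length(f$taps, 33L)
  Hpass <- abs(fir_response(f, seq(0, 0.01, length.out = 50)))
  expect_lt(max(abs(20 * log10(Hpass))), 1)
  Hstop <- abs(fir_response(f, seq(0.3, 1, length.out = 200)))
  achieved <- max(Hstop)                       # the design's achieved attenuation
  expect_lte(abs(fir_response(f, 0.3)), achieved + 1e-12)
  expect_lt(achieved, 1e-3)
})

test_that("zero-phase filtering rejects DC through the notch and keeps it through the low-pass", {
  g <- small_grids(64L)
  const <- deer_trace(rep(0.8, 64), g$tgrid, "noisy")
  notch <- design_fir(default_filter_specs("small")$notch)
  lp <- design_fir(default_filter_specs("small")$lowpass)
  expect_lt(max(abs(apply_filter(const, notch)$values)), 1e-3 * 0.8)
  expect_equal(apply_filter(const, lp)$values, const$values, tolerance = 1e-3)
  expect_error(apply_filter(rep(1, 10), notch), "too short")

  # stopband sinusoid attenuated at least by the squared measured response
  n <- 256L
  f_test <- 0.8
  x <- sin(pi * f_test * (0:(n - 1)))
  y <- apply_filter(x, lp)
  gain <- abs(fir_response(lp, f_test))^2
  expect_lt(sqrt(mean(y[64:192]^2)), max(gain * sqrt(mean(x^2)) * 10, 1e-6))
})

test_that("zero-phase filtering preserves oscillation phase", {
  n <- 256L
  lp <- design_fir(fir_filter_spec("lowpass", 32, 0.1, 0.4))
  x <- cos(pi * 0.05 * (0:(n - 1)))
  y <- apply_filter(x, lp)
  # in-band cosine passes with unit gain and no shift
  expect_equal(y[32:224], x[32:224], tolerance = 1e-2)
})

test_that("the regularized pseudoinverse satisfies its closed forms and normal equations", {
  set.seed(1)
  targets <- matrix(rnorm(6 * 8), 6, 8)
  expect_equal(build_transform(diag(8), targets, 0)$t_matrix, targets)
  expect_equal(build_transform(diag(8), targets, 1)$t_matrix, targets / 2)

  # random overdetermined case against an independent QR route on the
  # Tikhonov-augmented least-squares system
  Fm <- matrix(rnorm(10 * 40), 10, 40)
  P <- matrix(rnorm(7 * 40), 7, 40)
  lam <- 0.3
  tr <- build_transform(Fm, P, lam)
  aug <- rbind(t(Fm), sqrt(lam) * diag(10))
  rhs <- rbind(t(P), matrix(0, 10, 7))
  oracle <- t(qr.solve(aug, rhs))
  expect_equal(tr$t_matrix, oracle, tolerance = 1e-8)

  # rank-deficient without regularization: actionable error
  Fs <- matrix(1, 4, 5)
  expect_error(build_transform(Fs, matrix(1, 3, 5), 0), "lambda > 0")
  expect_error(build_transform(Fm, P[, 1:10], 1), "column counts")
})

test_that("the L-curve picks a lambda near the true-error optimum", {
  # ill-posed synthetic problem: smooth kernel, noisy data, known truth
  k <- small_kernel(32L)
  cfg <- synthetic_config(sigma = c(0.05, 0.05))
  ds <- generate_dataset(60, k, cfg, seed = 17)
  grid <- 10^seq(-6, 2, length.out = 40)
  lam <- lcurve_lambda(ds$inputs, ds$targets, grid)
  # residual norm must rise and solution norm fall along the grid
  lc <- attr(lam, "lcurve")
  expect_true(all(diff(lc$residual_norm) >= -1e-8))
  expect_true(all(diff(lc$solution_norm) <= 1e-8))
  # exhaustive true-error scan on independent noiseless data; the error is
  # flat over a range of lambdas, so the oracle is the near-optimal set
  # (within 10% of the minimal error) and the selection must land within
  # one decade of it
  ds_test <- generate_dataset(100, k, synthetic_config(sigma = c(0, 0)),
                              seed = 23)
  errs <- vapply(grid, function(l) {
    Tm <- build_transform(ds$inputs, ds$targets, l)$t_matrix
    norm(Tm %*% ds_test$inputs - ds_test$targets, "F")
  }, 1)
  good <- grid[errs <= 1.1 * min(errs)]
  expect_lte(min(abs(log10(as.numeric(lam) / good))), 1)
  expect_warning(l1 <- lcurve_lambda(ds$inputs, ds$targets, 0.1), "fewer than 3")
  expect_equal(as.numeric(l1), 0.1)
})

test_that("transform norm stays bounded as noise grows (regularization regularizes)", {
  k <- small_kernel(32L)
  norms <- vapply(c(0.005, 0.02, 0.08), function(sig) {
    cfg <- synthetic_config(sigma = c(sig, sig))
    ds <- generate_dataset(200, k, cfg, seed = 31)
    lam <- lcurve_lambda(ds$inputs, ds$targets)
    norm(build_transform(ds$inputs, ds$targets, as.numeric(lam))$t_matrix, "F")
  }, 1)
  # more noise must not inflate the fitted operator
  expect_lte(norms[3], 2 * norms[1])
})

test_that("the replica pipeline recovers known peaks and handles degenerate input", {
  k <- small_kernel(64L)
  rep_ <- train_replica(k, n_pairs = 400L, seed = 3L)
  dr <- k$dgrid$r[2] - k$dgrid$r[1]
  hits <- 0L
  for (s in 1:10) {
    cfg <- synthetic_config(n_components = c(1L, 1L))
    p <- sample_distribution(k$dgrid, cfg, seed = 400 + s)
    clean <- fredholm_forward(p, k)
    set.seed(500 + s)
    tr <- corrupt_trace(clean, stats::runif(1, .2, .5), stats::runif(1, 0, .15), 0)
    est <- replica_pipeline(tr, rep_)
    truth_peak <- k$dgrid$r[which.max(p$values)]
    est_peak <- k$dgrid$r[which.max(est$values)]
    if (abs(est_peak - truth_peak) <= dr + 1e-12) hits <- hits + 1L
  }
  expect_gte(hits, 8L)

  # an all-zero trace yields a zero estimate, renormalization skipped
  z <- replica_pipeline(rep(0, 64), rep_)
  expect_false(attr(z, "renormalized"))
  expect_equal(as.numeric(z), rep(0, 64))

  # linear up to the final clip
  x <- corrupt_trace(fredholm_forward(sample_distribution(k$dgrid, seed = 1), k),
                     0.3, 0.05, 0.01, seed = 2)$values
  lin <- function(v) as.numeric(rep_$transform$t_matrix %*%
    apply_filter(apply_filter(v, rep_$filters$notch), rep_$filters$lowpass))
  expect_equal(lin(2.5 * x), 2.5 * lin(x), tolerance = 1e-10)
})
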