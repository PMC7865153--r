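# Synthetic data generator: stands in for a measured training database of
# distance distributions and the corrupted dipolar traces they produce.

#' Default synthetic-data configuration
#'
#' Sampling ranges for the generator. Distances are restricted to the window
#' a 3.2 us trace can actually determine (roughly r <= (52 MHz us t_max/2)^(1/3)
#' nm by the usual two-period rule), widths and modulation depths are typical
#' of nitroxide-labelled proteins, and the background is a single exponential
#' (3-D homogeneous spin bath).
#'
#' @param n_components integer range of Gaussian component counts.
#' @param position range of component centres (nm).
#' @param width range of component standard deviations (nm).
#' @param amplitude range of (pre-normalization) component amplitudes.
#' @param depth range of modulation depths, inside (0, 1).
#' @param k_bg range of background decay rates (us^-1), nonnegative.
#' @param sigma range of Gaussian noise levels, nonnegative.
#' @return A named list of ranges.
#' @export
synthetic_config <- function(n_components = c(1L, 3L),
                             position = c(2, 4.5),
                             width = c(0.15, 0.5),
                             amplitude = c(0.2, 1),
                             depth = c(0.2, 0.5),
                             k_bg = c(0, 0.15),
                             sigma = c(0.002, 0.02)) {
  cfg <- list(n_components = as.integer(n_components), position = position,
              width = width, amplitude = amplitude, depth = depth,
              k_bg = k_bg, sigma = sigma)
  if (any(cfg$depth <= 0) || any(cfg$depth > 1)) {
    stop("modulation depth range must lie inside (0, 1]")
  }
  if (any(cfg$k_bg < 0) || any(cfg$sigma < 0)) {
    stop("background rate and noise level must be nonnegative")
  }
  cfg
}

# deterministic seed derivation; doubles are exact well past 48271 * 2^31
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt)) %% 2147483629)
}

#' Sample a random distance distribution
#'
#' Mixture of 1-3 Gaussians truncated to the grid and renormalized, the
#' simplest family reproducing the multi-peak distributions seen in practice.
#'
#' @param grid a [distance_grid()].
#' @param params a [synthetic_config()].
#' @param seed integer seed; the draw is a pure function of it.
#' @return A [distance_distribution()].
#' @export
sample_distribution <- function(grid, params = synthetic_config(), seed) {
  stopifnot(inherits(grid, "distance_grid"))
  if (any(params$position < grid$r_min) || any(params$position > grid$r_max)) {
    stop("component position range must lie within the distance grid")
  }
  set.seed(seed)
  ncomp <- sample(seq(params$n_components[1], params$n_components[2]), 1L)
  pos <- stats::runif(ncomp, params$position[1], params$position[2])
  wid <- stats::runif(ncomp, params$width[1], params$width[2])
  amp <- stats::runif(ncomp, params$amplitude[1], params$amplitude[2])
  v <- rep(0, grid$n)
  for (i in seq_len(ncomp)) v <- v + amp[i] * stats::dnorm(grid$r, pos[i], wid[i])
  distance_distribution(v, grid, normalize = TRUE)
}

#' Corrupt a clean form factor
#'
#' Composes the standard DEER trace model V(t) = B(t) (1 - depth (1 - Gamma(t)))
#' + eps with exponential background B(t) = exp(-k_bg t) and iid Gaussian noise.
#'
#' @param clean a clean form-factor [deer_trace()].
#' @param depth modulation depth in (0, 1).
#' @param k_bg background decay rate (us^-1), nonnegative.
#' @param sigma noise standard deviation, nonnegative.
#' @param seed integer seed for the noise draw.
#' @return A [deer_trace()] of kind `noisy` (or `with_baseline` when sigma = 0).
#' @export
corrupt_trace <- function(clean, depth, k_bg, sigma, seed = 0L) {
  stopifnot(inherits(clean, "deer_trace"))
  if (!(depth > 0 && depth <= 1)) stop("modulation depth must lie in (0, 1]")
  if (k_bg < 0) stop("background rate must be nonnegative")
  if (sigma < 0) stop("noise level must be nonnegative")
  tt <- clean$grid$t
  v <- exp(-k_bg * tt) * (1 - depth * (1 - clean$values))
  if (sigma > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, sigma)
  }
  deer_trace(v, clean$grid, kind = if (sigma > 0) "noisy" else "with_baseline")
}

#' Generate a paired training dataset
#'
#' Draws `n_records` distributions, pushes them through the Fredholm forward
#' transform and corrupts the traces with per-record nuisance parameters.
#' Per-record seeds derive deterministically from the master seed, so the whole
#' dataset is a pure function of `seed`.
#'
#' @param n_records number of records, at least 1.
#' @param kernel a [build_kernel()] result fixing both grids.
#' @param config a [synthetic_config()].
#' @param seed master integer seed.
#' @return An object of class `deer_dataset`: `inputs` (time points x records),
#'   `targets` (distance points x records, densities per nm), `records`
#'   (per-record nuisance parameters and seeds), plus both grids.
#' @export
generate_dataset <- function(n_records, kernel, config = synthetic_config(),
                             seed = 1L) {
  stopifnot(inherits(kernel, "dipolar_kernel"))
  n_records <- as.integer(n_records)
  if (n_records < 1L) stop("n_records must be at least 1")

  set.seed(derive_seed(seed, 1L))
  depth <- stats::runif(n_records, config$depth[1], config$depth[2])
  k_bg  <- stats::runif(n_records, config$k_bg[1], config$k_bg[2])
  sigma <- stats::runif(n_records, config$sigma[1], config$sigma[2])

  nt <- kernel$tgrid$n; nr <- kernel$dgrid$n
  inputs <- matrix(0, nt, n_records)
  targets <- matrix(0, nr, n_records)
  records <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    dist_seed <- derive_seed(seed, 2L * i)
    noise_seed <- derive_seed(seed, 2L * i + 1L)
    p <- sample_distribution(kernel$dgrid, config, dist_seed)
    clean <- fredholm_forward(p, kernel)
    noisy <- corrupt_trace(clean, depth[i], k_bg[i], sigma[i], noise_seed)
    inputs[, i] <- noisy$values
    targets[, i] <- p$values
    records[[i]] <- list(depth = depth[i], k_bg = k_bg[i], sigma = sigma[i],
                         dist_seed = dist_seed, noise_seed = noise_seed)
  }
  structure(list(inputs = inputs, targets = targets, records = records,
                 dgrid = kernel$dgrid, tgrid = kernel$tgrid, seed = seed),
            class = "deer_dataset")
}

#' @export
print.deer_dataset <- function(x, ...) {
  cat("DEER dataset: ", ncol(x$inputs), " records, ",
      nrow(x$inputs), " time points -> ", nrow(x$targets),
      " distance points\n", sep = "")
  invisible(x)
}
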