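# Diagnostic views of (descrambled) weight matrices: SVD signal libraries,
# frequency-domain conjugation, 2-D spectra, orthogonality scores.

# unitary DFT matrix, n x n
unitary_dft <- function(n) exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n) / sqrt(n)

# quadrant shift moving the zero-frequency bin to the centre
fftshift_index <- function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2))

#' SVD breakdown of a weight matrix
#'
#' W = U S V' read as: columns of V are the conjugate signals the matrix
#' expects to receive, S the amplification coefficients, columns of U the
#' signals it sends out in response. A deterministic sign convention is
#' applied (largest-magnitude entry of each left singular vector positive)
#' so that repeated runs and cross-implementation comparisons line up.
#'
#' @param W real matrix.
#' @return An object of class `svd_breakdown` with fields `u`, `s`, `v`.
#' @export
svd_breakdown <- function(W) {
  sv <- svd(W)
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  structure(list(u = sv$u, s = sv$d, v = sv$v), class = "svd_breakdown")
}

#' @export
print.svd_breakdown <- function(x, ...) {
  cat("SVD breakdown: ", nrow(x$u), " x ", nrow(x$v), ", rank-revealing s = [",
      format(x$s[1]), " ... ", format(x$s[length(x$s)]), "]\n", sep = "")
  invisible(x)
}

#' Frequency-domain conjugation of a weight matrix
#'
#' Inserting forward and backward Fourier transforms around y = W x connects
#' input and output spectra through F+ W F-. Unitary DFTs are used, so the
#' Frobenius norm is preserved; both axes are shifted to put zero frequency
#' at the centre. Rectangular matrices are conjugated with the DFT of each
#' dimension.
#'
#' @param W real or complex matrix.
#' @return An object of class `frequency_map` with the complex `map`, its
#'   `magnitude`, and zero-centred integer frequency axes `f_out`, `f_in`.
#' @export
frequency_conjugate <- function(W) {
  nr <- nrow(W); nc <- ncol(W)
  Fp <- unitary_dft(nr)
  Fm <- Conj(unitary_dft(nc))       # unitary inverse DFT
  M <- Fp %*% W %*% Fm
  M <- M[fftshift_index(nr), fftshift_index(nc)]
  axis <- function(n) (0:(n - 1))[fftshift_index(n)] - n * ((0:(n - 1))[fftshift_index(n)] >= n / 2)
  structure(list(map = M, magnitude = abs(M),
                 f_out = axis(nr), f_in = axis(nc)),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat("Frequency map: ", nrow(x$map), " x ", ncol(x$map),
      ", zero-frequency centred\n", sep = "")
  invisible(x)
}

#' Symmetrized 2-D Fourier magnitude of a weight matrix
#'
#' Magnitude of the two-dimensional DFT (unitary normalization) with both
#' axes shifted so the zero-frequency bin sits at the centre, which displays
#' the conjugate-symmetric pattern of a real matrix symmetrically about the
#' central point.
#'
#' @param W real matrix.
#' @return magnitude matrix (zero-frequency centred).
#' @export
sym_abs_fft2 <- function(W) {
  M <- stats::fft(W) / sqrt(length(W))
  abs(M)[fftshift_index(nrow(W)), fftshift_index(ncol(W))]
}

#' Row/column orthogonality score
#'
#' Normalizes the rows (or columns) to unit Euclidean norm, forms their Gram
#' matrix, and reports 1 minus the mean absolute off-diagonal entry: 1 for
#' exactly orthogonal families, 0 for rank-one (identical direction) families.
#'
#' @param W real matrix.
#' @param axis `"rows"` or `"cols"`.
#' @return list with `score` in \[0, 1\] and the normalized `gram` matrix.
#' @export
orthogonality_score <- function(W, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  A <- if (axis == "rows") W else t(W)
  nrm <- sqrt(rowSums(A^2))
  keep <- nrm > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-norm ", axis, " excluded from the score")
    A <- A[keep, , drop = FALSE]
    nrm <- nrm[keep]
  }
  G <- tcrossprod(A / nrm)
  off <- abs(G[row(G) != col(G)])
  list(score = 1 - mean(off), gram = G)
}

#' Cosine similarity of output signals to the Chebyshev basis
#'
#' Descriptive diagnostic for the output signal library of a descrambled
#' layer: mean absolute cosine similarity between the first `n_vec` left
#' singular vectors and their best-matching Chebyshev polynomials (first
#' kind, sampled on the output grid, orthonormalized by QR). Reported as a
#' number to look at, not a property to assert: the polynomials seen in
#' practice are recognisable but distorted.
#'
#' @param u matrix whose columns are output signals (e.g. `svd_breakdown(W)$u`).
#' @param n_vec how many leading vectors to score.
#' @param n_poly size of the Chebyshev dictionary.
#' @return list with per-vector best similarities and their mean.
#' @export
chebyshev_similarity <- function(u, n_vec = min(10L, ncol(u)), n_poly = 2L * n_vec) {
  n <- nrow(u)
  x <- seq(-1, 1, length.out = n)
  Tm <- sapply(0:(n_poly - 1), function(m) cos(m * acos(x)))
  Qm <- qr.Q(qr(Tm))
  best <- vapply(seq_len(n_vec), function(j) {
    v <- u[, j] / sqrt(sum(u[, j]^2))
    max(abs(crossprod(Qm, v)))
  }, numeric(1))
  list(similarity = best, mean = mean(best))
}

#' Align two maps over circular shifts of the descrambled axis
#'
#' Descrambling is reproducible across training runs only up to circular
#' shifts, reversal and overall sign of the descrambled (link) dimension.
#' This helper reports the maximum Pearson correlation between two maps over
#' all circular row shifts, with and without row reversal.
#'
#' @param A,B numeric matrices of equal size (e.g. frequency-map magnitudes).
#' @return the maximal correlation.
#' @export
aligned_map_correlation <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("maps must have equal dimensions")
  n <- nrow(B)
  best <- -1
  a <- as.vector(A)
  for (flip in c(FALSE, TRUE)) {
    Bf <- if (flip) B[n:1, , drop = FALSE] else B
    for (sh in 0:(n - 1)) {
      Bs <- Bf[((seq_len(n) - 1 + sh) %% n) + 1, , drop = FALSE]
      best <- max(best, stats::cor(a, as.vector(Bs)))
    }
  }
  best
}
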