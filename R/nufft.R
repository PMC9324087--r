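# Kaiser-Bessel gridding NUFFT (type 2 and its exact adjoint).
#
# Conventions, fixed once and asserted in the tests:
#   * image pixels are 0-based with the DC pixel at index N/2, so the
#     centered coordinate is x~ = x - N/2;
#   * a k-space sample at (kx, ky) cycles/pixel evaluates
#       S(k) = sum_x I(x) exp(-2i pi (kx x~ + ky y~))
#     with no additional normalization;
#   * the oversampled grid has Ng = oversample * N points per dimension and
#     the adjoint is the exact conjugate transpose of the forward map, so
#     forward/adjoint dot tests hold to machine precision independent of
#     kernel accuracy.

kb_kernel <- function(u, width, beta) {
  t <- 1 - (2 * u / width)^2
  w <- numeric(length(u))
  ok <- t > 0
  w[ok] <- besselI(beta * sqrt(t[ok]), 0) / besselI(beta, 0)
  w
}

# numerical Fourier transform of the kernel, used for deapodization;
# xi in cycles per grid unit
kb_kernel_ft <- function(xi, width, beta, n_quad = 4001) {
  u <- seq(-width / 2, width / 2, length.out = n_quad)
  cu <- kb_kernel(u, width, beta)
  du <- u[2] - u[1]
  vapply(xi, function(f) sum(cu * cos(2 * pi * u * f)) * du, numeric(1))
}

#' Plan a gridding NUFFT
#'
#' Precomputes the sparse Kaiser-Bessel interpolation matrix, the
#' oversampled-grid embedding and the deapodization image for a fixed set
#' of k-space sample coordinates.  The kernel shape parameter follows the
#' standard width/oversampling tradeoff (`beta = pi * sqrt((w/s)^2 *
#' (s - 0.5)^2 - 0.8)` for width `w` and oversampling `s`); deapodization
#' uses the numerically integrated kernel transform, and the accuracy
#' contract of the resulting operator is checked against a dense discrete
#' Fourier oracle in the package tests rather than assumed from the kernel.
#'
#' @param coords M x 2 matrix of (kx, ky) in cycles/pixel, within
#'   \[-0.5, 0.5).
#' @param n image matrix size N (square images).
#' @param oversample grid oversampling factor (default 2).
#' @param width kernel width in oversampled grid units (default 8).
#' @return object of class `mrf_nufft_plan`.
#' @export
nufft_plan <- function(coords, n, oversample = 2, width = 8) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, all(is.finite(coords)))
  n <- as.integer(n)
  ng <- as.integer(round(oversample * n))
  if (ng %% 2 != 0) ng <- ng + 1L
  M <- nrow(coords)
  beta <- pi * sqrt((width / oversample)^2 * (oversample - 0.5)^2 - 0.8)

  u <- coords * ng  # sample positions in grid units
  half <- width / 2
  # W consecutive integer neighbors per dimension around each sample
  base_x <- floor(u[, 1]) - (width %/% 2) + 1L
  base_y <- floor(u[, 2]) - (width %/% 2) + 1L
  offs <- seq_len(width) - 1L

  # triplets for the M x ng^2 interpolation matrix
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  wx <- matrix(0, M, width)
  wy <- matrix(0, M, width)
  gx <- matrix(0L, M, width)
  gy <- matrix(0L, M, width)
  for (a in seq_len(width)) {
    jx <- base_x + offs[a]
    jy <- base_y + offs[a]
    wx[, a] <- kb_kernel(u[, 1] - jx, width, beta)
    wy[, a] <- kb_kernel(u[, 2] - jy, width, beta)
    gx[, a] <- jx %% ng
    gy[, a] <- jy %% ng
  }
  ridx <- seq_len(M)
  for (a in seq_len(width)) {
    for (b in seq_len(width)) {
      w <- wx[, a] * wy[, b]
      keep <- w != 0
      if (!any(keep)) next
      rows <- c(rows, ridx[keep])
      cols <- c(cols, (gx[keep, a] + gy[keep, b] * ng) + 1L)
      vals <- c(vals, w[keep])
    }
  }
  P <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(M, ng * ng))

  # embedding of the N x N image into the oversampled grid: pixel x maps to
  # grid index (x - N/2) mod Ng, so the plain FFT already evaluates
  # exp(-2i pi g x~ / Ng) for every integer frequency g
  embed <- ((seq_len(n) - 1L) - n %/% 2L) %% ng + 1L

  xt <- (seq_len(n) - 1L) - n %/% 2L
  apod1d <- kb_kernel_ft(xt / ng, width, beta)
  apod <- outer(apod1d, apod1d)

  structure(list(P = P, n = n, ng = ng, M = M, width = width, beta = beta,
                 oversample = oversample, embed = embed, apod = apod,
                 coords = coords),
            class = "mrf_nufft_plan")
}

#' @export
print.mrf_nufft_plan <- function(x, ...) {
  cat(sprintf("NUFFT plan: %d samples, N = %d (grid %d), kernel width %d\n",
              x$M, x$n, x$ng, x$width))
  invisible(x)
}

# real-sparse times complex-dense
sp_mult <- function(P, X) {
  if (is.complex(X)) {
    as.matrix(P %*% Re(X)) + 1i * as.matrix(P %*% Im(X))
  } else {
    as.matrix(P %*% X)
  }
}

sp_tmult <- function(P, X) {
  if (is.complex(X)) {
    as.matrix(Matrix::crossprod(P, Re(X))) +
      1i * as.matrix(Matrix::crossprod(P, Im(X)))
  } else {
    as.matrix(Matrix::crossprod(P, X))
  }
}

#' Apply a NUFFT plan
#'
#' `nufft_forward` maps one or more N x N images to their k-space samples;
#' `nufft_adjoint` is the exact conjugate-transpose map.  Multi-channel
#' input is given as an N^2 x n_channels matrix (or an N x N matrix for a
#' single channel).
#'
#' @param plan an [nufft_plan()].
#' @param x for the forward map an N x N image or N^2 x C matrix; for the
#'   adjoint an M-vector or M x C matrix of k-space samples.
#' @return forward: M x C matrix (M-vector for one channel); adjoint:
#'   N^2 x C matrix (N x N image for one channel).
#' @export
nufft_forward <- function(plan, x) {
  single <- is.matrix(x) && nrow(x) == plan$n && ncol(x) == plan$n
  X <- if (single) matrix(x, ncol = 1) else as.matrix(x)
  stopifnot(nrow(X) == plan$n^2)
  nch <- ncol(X)
  Fmat <- matrix(0 + 0i, plan$ng^2, nch)
  E <- matrix(0 + 0i, plan$ng, plan$ng)
  for (ch in seq_len(nch)) {
    E[] <- 0
    E[plan$embed, plan$embed] <- matrix(X[, ch], plan$n, plan$n) / plan$apod
    Fmat[, ch] <- stats::fft(E)
  }
  Y <- sp_mult(plan$P, Fmat)
  if (single || nch == 1) drop(Y) else Y
}

#' @rdname nufft_forward
#' @export
nufft_adjoint <- function(plan, x) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  stopifnot(nrow(X) == plan$M)
  nch <- ncol(X)
  G <- sp_tmult(plan$P, X)
  out <- matrix(0 + 0i, plan$n^2, nch)
  for (ch in seq_len(nch)) {
    B <- stats::fft(matrix(G[, ch], plan$ng, plan$ng), inverse = TRUE)
    out[, ch] <- as.vector(B[plan$embed, plan$embed] / plan$apod)
  }
  if (nch == 1 && !is.matrix(x)) matrix(out, plan$n, plan$n) else out
}

#' Fuse the temporal subspace into the gridding operator
#'
#' Builds the combined projection-plus-gridding operator of the subspace
#' forward model: one sparse interpolation matrix over the stacked spokes
#' of all frames is precomputed once, and applying the operator touches
#' only the K coefficient channels (K FFTs plus one sparse multiply and a
#' frame-wise weighting by the subspace basis), so the per-application cost
#' is independent of the train length T beyond the fixed sample count.
#' Its action equals projecting the K coefficient images to T frame images
#' with the basis and gridding each frame at its own spoke.
#'
#' @param subspace an [compute_subspace()] result (basis T x K).
#' @param sampling an [kt_sampling()] object; its T must equal the basis
#'   rows.
#' @param n image matrix size.
#' @param oversample,width gridding parameters, see [nufft_plan()].
#' @return object of class `mrf_fused_op` with elements `forward(kimgs)`
#'   (N x N x K array to an M-vector of k-space samples ordered sample-
#'   within-spoke, then frame) and `adjoint(y)`.
#' @export
combine_gridding_with_subspace <- function(subspace, sampling, n,
                                           oversample = 2, width = 8) {
  stopifnot(inherits(subspace, "mrf_subspace"), inherits(sampling, "mrf_sampling"))
  if (nrow(subspace$basis) != sampling$n_frames)
    stop("subspace basis rows must equal the number of frames")
  plan <- nufft_plan(all_spoke_coordinates(sampling), n,
                     oversample = oversample, width = width)
  K <- subspace$rank
  phi_exp <- subspace$basis[rep(seq_len(sampling$n_frames),
                                each = sampling$readout_samples), , drop = FALSE]
  force(plan)
  fwd <- function(kimgs) {
    V <- nufft_forward(plan, matrix(kimgs, n * n, K))
    V <- if (is.matrix(V)) V else matrix(V, ncol = 1)
    rowSums(V * phi_exp)
  }
  adj <- function(y) {
    B <- Conj(phi_exp) * as.complex(y)
    array(nufft_adjoint(plan, B), dim = c(n, n, K))
  }
  structure(list(forward = fwd, adjoint = adj, plan = plan,
                 phi_exp = phi_exp, rank = K, n = n,
                 n_frames = sampling$n_frames,
                 readout_samples = sampling$readout_samples),
            class = "mrf_fused_op")
}
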