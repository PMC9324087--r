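#' Reconstruction configuration
#'
#' Parameters of the two reconstruction paths.  Defaults follow the
#' validated pipeline: unaccelerated (R = 1) data are solved with 20 plain
#' conjugate-gradient iterations and no regularization; accelerated data
#' with 8 ADMM iterations of 5 CG steps each, locally-low-rank patches of
#' 8 x 8 pixels and `lambda = 1e-4`.  The regularization weight is
#' interpreted on normalized data: before solving, the right-hand side
#' `E^H y` is scaled so its largest magnitude is 1, which makes the printed
#' lambda transferable across data scalings.
#'
#' @param lambda_llr locally-low-rank regularization weight (>= 0).
#' @param patch_size LLR patch side in pixels.
#' @param n_admm_iters number of outer ADMM iterations.
#' @param n_cg_iters CG iterations per ADMM x-update.
#' @param n_cg_iters_linear CG iterations of the unregularized (R = 1)
#'   reconstruction.
#' @param admm_rho ADMM penalty parameter, on the normalized data scale.
#' @param cg_tolerance relative residual at which CG stops early.
#' @param patch_shift_mode `"fixed"` keeps the non-overlapping patch tiling
#'   anchored at the image origin (the exact proximal map);
#'   `"cycled"` shifts the tiling by one pixel per ADMM iteration.
#' @param joint_replicates when TRUE (default) the R aliased slices of a
#'   group share one patch matrix (patch pixels stacked over replicates x
#'   K), coupling the replicates through the low-rank model; when FALSE
#'   each replicate is thresholded independently.
#' @return object of class `mrf_recon_config`.
#' @export
recon_config <- function(lambda_llr = 1e-4,
                         patch_size = 8,
                         n_admm_iters = 8,
                         n_cg_iters = 5,
                         n_cg_iters_linear = 20,
                         admm_rho = 1e-2,
                         cg_tolerance = 1e-8,
                         patch_shift_mode = c("fixed", "cycled"),
                         joint_replicates = TRUE) {
  if (lambda_llr < 0) stop("lambda_llr must be >= 0")
  if (patch_size < 1) stop("patch_size must be >= 1")
  if (n_admm_iters < 1 || n_cg_iters < 1 || n_cg_iters_linear < 1)
    stop("iteration counts must be >= 1")
  if (admm_rho <= 0) stop("admm_rho must be > 0")
  structure(list(lambda_llr = lambda_llr,
                 patch_size = as.integer(patch_size),
                 n_admm_iters = as.integer(n_admm_iters),
                 n_cg_iters = as.integer(n_cg_iters),
                 n_cg_iters_linear = as.integer(n_cg_iters_linear),
                 admm_rho = admm_rho,
                 cg_tolerance = cg_tolerance,
                 patch_shift_mode = match.arg(patch_shift_mode),
                 joint_replicates = isTRUE(joint_replicates)),
            class = "mrf_recon_config")
}

#' @export
print.mrf_recon_config <- function(x, ...) {
  cat(sprintf(paste0("Recon config: lambda = %g, patch %d x %d, ",
                     "%d ADMM x %d CG (linear: %d CG), rho = %g\n"),
              x$lambda_llr, x$patch_size, x$patch_size,
              x$n_admm_iters, x$n_cg_iters, x$n_cg_iters_linear, x$admm_rho))
  invisible(x)
}

# CG on the normal equations (E^H E + rho I) x = rhs, from x0.
cg_normal <- function(normal_fun, rhs, x0, niter, tol = 1e-8, rho = 0) {
  x <- x0
  apply_op <- function(v) {
    out <- normal_fun(v)
    if (rho > 0) out <- out + rho * v
    out
  }
  r <- rhs - apply_op(x)
  p <- r
  rs <- sum(Mod(r)^2)
  rs0 <- max(rs, .Machine$double.xmin)
  resids <- numeric(0)
  for (it in seq_len(niter)) {
    Ap <- apply_op(p)
    denom <- Re(sum(Conj(p) * Ap))
    if (!is.finite(denom) || denom <= 0) break
    a <- rs / denom
    x <- x + a * p
    r <- r - a * Ap
    rs_new <- sum(Mod(r)^2)
    if (!is.finite(rs_new))
      stop("conjugate gradient diverged (non-finite iterate)")
    resids <- c(resids, sqrt(rs_new / rs0))
    if (sqrt(rs_new / rs0) <= tol) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  attr(x, "cg_resid") <- resids
  x
}

#' Unregularized conjugate-gradient reconstruction
#'
#' Approximately minimizes `||E alpha - y||_2^2` by conjugate gradients on
#' the normal equations, starting from zero.  This is the reconstruction
#' used for fully partition-encoded (R = 1) data; it is also usable as an
#' unregularized baseline for accelerated data.
#'
#' @param y slice-group data matrix ((readout * T) x n_coils), e.g. one
#'   element of [hybrid_decode()]'s `groups`.
#' @param E operator from [subspace_operator()].
#' @param config an [recon_config()]; `n_cg_iters_linear` and
#'   `cg_tolerance` are used.
#' @return coefficient array (N, N, K, R) with attribute `cg_resid`, the
#'   relative normal-equation residual per iteration.
#' @export
cg_linear_recon <- function(y, E, config = recon_config()) {
  rhs <- E$adjoint(y)
  x0 <- array(0 + 0i, dim = dim(rhs))
  cg_normal(E$normal, rhs, x0, config$n_cg_iters_linear, config$cg_tolerance)
}

#' Proximal map of the locally-low-rank penalty
#'
#' Exact proximal operator of `threshold * sum_r ||R_r(.)||_*` for a fixed
#' non-overlapping patch tiling: each patch of every coefficient image is
#' rearranged into a (patch pixels \[x replicates\]) x K matrix, its
#' singular values are soft-thresholded, and the patch is reassembled.
#' Images whose side is not a multiple of the patch size are zero-padded
#' for the tiling and cropped afterwards.
#'
#' @param alpha coefficient array (N, N, K) or (N, N, K, R).
#' @param threshold soft-threshold applied to the singular values (>= 0).
#' @param patch_size patch side in pixels.
#' @param joint_replicates stack the R replicates into one patch matrix
#'   (default) instead of thresholding each replicate separately.
#' @param shift integer tiling offset in pixels (used by the cycled patch
#'   mode); the tiling is shifted circularly.
#' @return array of the same shape as `alpha`.
#' @export
llr_prox <- function(alpha, threshold, patch_size,
                     joint_replicates = TRUE, shift = 0L) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (threshold == 0) return(alpha)
  orig_d <- dim(alpha)
  d <- orig_d
  if (length(d) == 3) { dim(alpha) <- c(d, 1L); d <- dim(alpha) }
  stopifnot(length(d) == 4)
  n1 <- d[1]; n2 <- d[2]; K <- d[3]; R <- d[4]
  p <- as.integer(patch_size)
  if (shift != 0) {
    idx1 <- ((seq_len(n1) - 1 + shift) %% n1) + 1
    idx2 <- ((seq_len(n2) - 1 + shift) %% n2) + 1
    alpha <- alpha[idx1, idx2, , , drop = FALSE]
  }
  m1 <- ceiling(n1 / p) * p
  m2 <- ceiling(n2 / p) * p
  padded <- n1 != m1 || n2 != m2
  if (padded) {
    tmp <- array(0 + 0i, dim = c(m1, m2, K, R))
    tmp[seq_len(n1), seq_len(n2), , ] <- alpha
    alpha <- tmp
  }
  for (bi in seq_len(m1 %/% p)) {
    ri <- ((bi - 1) * p + 1):(bi * p)
    for (bj in seq_len(m2 %/% p)) {
      rj <- ((bj - 1) * p + 1):(bj * p)
      if (joint_replicates) {
        blk <- alpha[ri, rj, , , drop = FALSE]
        Mp <- matrix(aperm(blk, c(1, 2, 4, 3)), p * p * R, K)
        Mp <- svt(Mp, threshold)
        blk <- aperm(array(Mp, dim = c(p, p, R, K)), c(1, 2, 4, 3))
        alpha[ri, rj, , ] <- blk
      } else {
        for (j in seq_len(R)) {
          Mp <- matrix(alpha[ri, rj, , j], p * p, K)
          alpha[ri, rj, , j] <- array(svt(Mp, threshold), dim = c(p, p, K))
        }
      }
    }
  }
  if (padded) alpha <- alpha[seq_len(n1), seq_len(n2), , , drop = FALSE]
  if (shift != 0) {
    inv1 <- order(idx1); inv2 <- order(idx2)
    alpha <- alpha[inv1, inv2, , , drop = FALSE]
  }
  dim(alpha) <- orig_d
  alpha
}

# singular-value soft-thresholding
svt <- function(X, thr) {
  sv <- svd(X)
  s <- pmax(sv$d - thr, 0)
  keep <- s > 0
  if (!any(keep)) return(X * 0)
  sv$u[, keep, drop = FALSE] %*%
    (s[keep] * Conj(t(sv$v[, keep, drop = FALSE])))
}

# total LLR nuclear norm of a coefficient array (fixed tiling from origin)
llr_nuclear_norm <- function(alpha, patch_size, joint_replicates = TRUE) {
  d <- dim(alpha)
  if (length(d) == 3) { dim(alpha) <- c(d, 1L); d <- dim(alpha) }
  n1 <- d[1]; n2 <- d[2]; K <- d[3]; R <- d[4]
  p <- as.integer(patch_size)
  m1 <- ceiling(n1 / p) * p
  m2 <- ceiling(n2 / p) * p
  if (n1 != m1 || n2 != m2) {
    tmp <- array(0 + 0i, dim = c(m1, m2, K, R))
    tmp[seq_len(n1), seq_len(n2), , ] <- alpha
    alpha <- tmp
  }
  total <- 0
  for (bi in seq_len(m1 %/% p)) {
    ri <- ((bi - 1) * p + 1):(bi * p)
    for (bj in seq_len(m2 %/% p)) {
      rj <- ((bj - 1) * p + 1):(bj * p)
      if (joint_replicates) {
        Mp <- matrix(aperm(alpha[ri, rj, , , drop = FALSE], c(1, 2, 4, 3)),
                     p * p * R, K)
        total <- total + sum(svd(Mp, nu = 0, nv = 0)$d)
      } else {
        for (j in seq_len(R))
          total <- total + sum(svd(matrix(alpha[ri, rj, , j], p * p, K),
                                   nu = 0, nv = 0)$d)
      }
    }
  }
  total
}

#' Objective of the regularized inverse problem
#'
#' Evaluates `||E alpha - y||_2^2 + lambda * sum_r ||R_r alpha||_*` for a
#' given coefficient estimate (on the raw data scale).
#'
#' @inheritParams cg_linear_recon
#' @param alpha coefficient array (N, N, K, R).
#' @param lambda regularization weight.
#' @param patch_size LLR patch side.
#' @param joint_replicates see [llr_prox()].
#' @export
recon_objective <- function(alpha, y, E, lambda, patch_size,
                            joint_replicates = TRUE) {
  resid <- E$forward(alpha) - y
  sum(Mod(resid)^2) +
    lambda * llr_nuclear_norm(alpha, patch_size, joint_replicates)
}

#' Spectral norm of the forward model
#'
#' Estimates `||E||` (the square root of the largest eigenvalue of
#' `E^H E`) by power iteration from a deterministic start vector.  Used to
#' put the inverse problem on the normalized scale on which the
#' regularization weight is interpreted.
#'
#' @param E operator from [subspace_operator()].
#' @param n_iters power iterations (default 15).
#' @param v0 optional start array; defaults to a fixed pseudo-random array
#'   derived from a constant seed, keeping the estimate deterministic.
#' @return scalar estimate of the operator 2-norm.
#' @export
operator_norm <- function(E, n_iters = 15, v0 = NULL) {
  if (is.null(v0)) {
    nel <- E$n^2 * E$rank * E$n_replicates
    v0 <- withr::with_seed(271828L, {
      array(complex(real = stats::rnorm(nel), imaginary = stats::rnorm(nel)),
            dim = c(E$n, E$n, E$rank, E$n_replicates))
    })
  }
  v <- v0 / sqrt(sum(Mod(v0)^2))
  lam <- 0
  for (i in seq_len(n_iters)) {
    w <- E$normal(v)
    lam <- sqrt(sum(Mod(w)^2))
    if (lam == 0) return(0)
    v <- w / lam
  }
  sqrt(lam)
}

#' ADMM reconstruction with locally-low-rank regularization
#'
#' Solves `min_x ||E x - y||_2^2 + lambda * sum_r ||R_r z||_*` subject to
#' `x = z` by the alternating direction method of multipliers: the x-update
#' runs `n_cg_iters` warm-started CG steps on
#' `(E^H E + rho I) x = E^H y + rho (z - u)`, the z-update applies
#' [llr_prox()] with threshold `lambda / rho`, and the scaled dual variable
#' is updated as `u <- u + x - z`.
#'
#' The problem is solved on a normalized scale: the operator is divided by
#' its spectral norm (so `E^H E` has unit norm) and the data are scaled so
#' that `max |E^H y| = 1`; `lambda` and `rho` are interpreted on that
#' scale, where the solution and its patch singular values are of order
#' one, and the result is scaled back on return.
#'
#' @inheritParams cg_linear_recon
#' @param verbose print per-iteration residuals.
#' @param op_norm precomputed [operator_norm()] of `E`; estimated when
#'   missing (it is identical across slice groups up to the mild variation
#'   of the coil maps, so one estimate can be shared).
#' @return coefficient array (N, N, K, R) with attribute `admm_log`, a
#'   data frame of per-iteration primal residuals and data-fidelity values
#'   (on the normalized scale).
#' @export
admm_llr_recon <- function(y, E, config = recon_config(), verbose = FALSE,
                           op_norm = NULL) {
  if (config$lambda_llr < 0) stop("lambda_llr must be >= 0")
  if (is.null(op_norm)) op_norm <- operator_norm(E)
  Ehy <- E$adjoint(y)
  L2 <- op_norm^2
  scale <- max(Mod(Ehy)) / L2   # data scale on the unit-norm-operator scale
  if (scale == 0 || op_norm == 0) {
    out <- array(0 + 0i, dim = dim(Ehy))
    attr(out, "admm_log") <- data.frame(iter = integer(0),
                                        primal_resid = numeric(0),
                                        data_fidelity = numeric(0))
    return(out)
  }
  # normalized problem: minimize ||(E/L) x - y/(L*scale)||^2 + penalties
  b <- Ehy / (L2 * scale)               # (E/L)^H applied to scaled data
  normal_hat <- function(v) E$normal(v) / L2
  rho <- config$admm_rho
  lam <- config$lambda_llr
  x <- array(0 + 0i, dim = dim(b))
  z <- x; u <- x
  log <- data.frame(iter = integer(0), primal_resid = numeric(0),
                    data_fidelity = numeric(0))
  y_hat_nrm2 <- sum(Mod(y)^2) / (op_norm * scale)^2
  for (it in seq_len(config$n_admm_iters)) {
    rhs <- b + rho * (z - u)
    x <- cg_normal(normal_hat, rhs, x, config$n_cg_iters,
                   config$cg_tolerance, rho = rho)
    if (any(!is.finite(Re(x)))) stop("ADMM diverged (non-finite iterate)")
    shift <- if (config$patch_shift_mode == "cycled") (it - 1L) %% config$patch_size else 0L
    z <- llr_prox(x + u, lam / rho, config$patch_size,
                  joint_replicates = config$joint_replicates, shift = shift)
    u <- u + x - z
    pr <- sqrt(sum(Mod(x - z)^2)) / max(sqrt(sum(Mod(x)^2)), .Machine$double.xmin)
    # ||(E/L) x - y_hat||^2 without an extra operator application:
    # = x^H normal_hat(x) - 2 Re<x, b> + ||y_hat||^2, using the CG cache-free form
    df <- Re(sum(Conj(x) * normal_hat(x))) - 2 * Re(sum(Conj(x) * b)) + y_hat_nrm2
    log <- rbind(log, data.frame(iter = it, primal_resid = pr,
                                 data_fidelity = df))
    if (verbose)
      message(sprintf("ADMM %2d: primal %.3e  data %.6e", it, pr, df))
  }
  out <- x * scale
  attr(out, "admm_log") <- log
  out
}
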