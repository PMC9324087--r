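#' Reconstruct quantitative maps from MRF k-space data
#'
#' The package's fitting entry point.  The acquisition is decoded into
#' independent aliased-slice groups ([hybrid_decode()]), each group's
#' subspace coefficient images are estimated by solving the regularized
#' least-squares inverse problem — plain conjugate gradients for fully
#' partition-encoded data (R = 1), ADMM with locally-low-rank
#' regularization for accelerated data — the coefficient images are
#' optionally denoised slice-wise by non-local means, and voxelwise T1/T2
#' are assigned by dot-product dictionary matching.
#'
#' @param kdata an [mrf_kspace()] acquisition.
#' @param dict a normalized [build_dictionary()] result whose sequence
#'   matches the acquisition.
#' @param coils an [mrf_coils()] object (e.g. from
#'   [estimate_sensitivities()] or the simulator's ground truth).
#' @param subspace temporal subspace; computed from `dict` at rank 5 when
#'   not supplied.
#' @param config an [recon_config()].
#' @param denoise apply non-local means to the coefficient images; default
#'   follows the pipeline (TRUE for R > 1, FALSE for R = 1).
#' @param nlm_patch,nlm_search non-local-means window sizes (pixels).
#' @param oversampling_fraction slice oversampling to crop from the
#'   matched maps (0 = none).
#' @param score_threshold matching validity threshold, see
#'   [match_dictionary()].
#' @param voxel_mm voxel dimensions recorded in the maps.
#' @param verbose print solver progress.
#' @return an object of class `mrf_recon`; see [coef.mrf_recon()],
#'   [fitted.mrf_recon()], [residuals.mrf_recon()], [plot.mrf_recon()].
#' @export
mrf_reconstruct <- function(kdata, dict, coils,
                            subspace = NULL,
                            config = recon_config(),
                            denoise = NULL,
                            nlm_patch = 3, nlm_search = 32,
                            oversampling_fraction = 0,
                            score_threshold = 0.1,
                            voxel_mm = c(1, 1, 1),
                            verbose = FALSE) {
  stopifnot(inherits(kdata, "mrf_kspace"), inherits(dict, "mrf_dictionary"),
            inherits(coils, "mrf_coils"))
  sampling <- kdata$sampling
  R <- sampling$reduction
  if (is.null(subspace)) subspace <- compute_subspace(dict, 5)
  if (is.null(denoise)) denoise <- R > 1
  n <- kdata$n
  K <- subspace$rank
  Nz <- sampling$n_partitions

  hybrid <- hybrid_decode(kdata)
  grp <- slice_groups(sampling)
  fused <- combine_gridding_with_subspace(subspace, sampling, n)

  alpha <- array(0 + 0i, dim = c(n, n, K, Nz))  # per true slice
  logs <- vector("list", grp$n_groups)
  op_norm <- NULL
  for (g in seq_len(grp$n_groups)) {
    if (verbose) message(sprintf("slice group %d / %d", g, grp$n_groups))
    E <- subspace_operator(subspace, coils, sampling, group = g, fused = fused)
    y <- hybrid$groups[[g]]
    if (R == 1) {
      ag <- cg_linear_recon(y, E, config)
      logs[[g]] <- list(cg_resid = attr(ag, "cg_resid"))
    } else {
      # the spectral norm is shared across groups (coil maps vary mildly)
      if (is.null(op_norm)) op_norm <- operator_norm(E)
      ag <- admm_llr_recon(y, E, config, verbose = verbose,
                           op_norm = op_norm)
      logs[[g]] <- list(admm = attr(ag, "admm_log"))
    }
    for (j in seq_len(R)) alpha[, , , grp$slices[g, j]] <- ag[, , , j]
  }

  if (denoise) {
    for (z in seq_len(Nz)) {
      for (k in seq_len(K)) {
        alpha[, , k, z] <- nlm_denoise(alpha[, , k, z],
                                       patch = nlm_patch, search = nlm_search)
      }
    }
  }

  # voxels x K, slices stacked along the third axis for matching
  coeff <- aperm(alpha, c(1, 2, 4, 3))
  maps <- match_dictionary(coeff, dict, subspace = subspace,
                           score_threshold = score_threshold,
                           voxel_mm = voxel_mm)
  if (oversampling_fraction > 0)
    maps <- crop_oversampled_slices(maps, oversampling_fraction)

  structure(list(alpha = alpha, maps = maps, dict = dict,
                 subspace = subspace, sampling = sampling,
                 config = config, denoised = denoise,
                 oversampling_fraction = oversampling_fraction,
                 solver = if (R == 1) "cg" else "admm_llr",
                 logs = logs, n = n, coils = coils,
                 call = match.call()),
            class = "mrf_recon")
}

#' @export
print.mrf_recon <- function(x, ...) {
  cat("MRF subspace reconstruction\n")
  cat(sprintf("  %d x %d x %d volume, K = %d, R = %d, solver: %s%s\n",
              x$n, x$n, x$sampling$n_partitions, x$subspace$rank,
              x$sampling$reduction, x$solver,
              if (x$denoised) " + NLM" else ""))
  print(x$maps)
  invisible(x)
}

#' @export
summary.mrf_recon <- function(object, ...) {
  res <- list(solver = object$solver,
              reduction = object$sampling$reduction,
              rank = object$subspace$rank,
              n_groups = length(object$logs),
              maps = object$maps)
  if (object$solver == "cg") {
    res$final_cg_resid <- vapply(object$logs, function(l)
      utils::tail(l$cg_resid, 1), numeric(1))
  } else {
    res$final_primal_resid <- vapply(object$logs, function(l)
      utils::tail(l$admm$primal_resid, 1), numeric(1))
  }
  class(res) <- "summary.mrf_recon"
  res
}

#' @export
print.summary.mrf_recon <- function(x, ...) {
  cat(sprintf("MRF reconstruction (%s, R = %d, K = %d, %d slice groups)\n",
              x$solver, x$reduction, x$rank, x$n_groups))
  if (!is.null(x$final_cg_resid))
    cat(sprintf("  final CG relative residuals: %s\n",
                paste(sprintf("%.2e", x$final_cg_resid), collapse = " ")))
  if (!is.null(x$final_primal_resid))
    cat(sprintf("  final ADMM primal residuals: %s\n",
                paste(sprintf("%.2e", x$final_primal_resid), collapse = " ")))
  print(x$maps)
  invisible(x)
}

#' Extract subspace coefficient images
#'
#' The K "singular value" coefficient images per slice — the quantities
#' the solver estimates.
#'
#' @param object an `mrf_recon` fit.
#' @param ... unused.
#' @return complex array (N, N, K, Nz).
#' @export
coef.mrf_recon <- function(object, ...) object$alpha

#' Extract fitted parameter maps
#'
#' @param object an `mrf_recon` fit.
#' @param ... unused.
#' @return the [parameter_maps()] object of the fit.
#' @export
fitted.mrf_recon <- function(object, ...) object$maps

#' k-space residuals of a reconstruction
#'
#' Re-applies the forward model to the estimated coefficients and returns
#' per-slice-group residual norms relative to the decoded data, a direct
#' check of data fidelity.
#'
#' @param object an `mrf_recon` fit.
#' @param kdata the acquisition that was reconstructed.
#' @param ... unused.
#' @return data frame with one row per slice group: `group`,
#'   `rel_residual`.
#' @export
residuals.mrf_recon <- function(object, kdata, ...) {
  stopifnot(inherits(kdata, "mrf_kspace"))
  hybrid <- hybrid_decode(kdata)
  grp <- slice_groups(object$sampling)
  fused <- combine_gridding_with_subspace(object$subspace, object$sampling,
                                          object$n)
  out <- data.frame(group = seq_len(grp$n_groups), rel_residual = NA_real_)
  for (g in seq_len(grp$n_groups)) {
    E <- subspace_operator(object$subspace, object$coils, object$sampling,
                           group = g, fused = fused)
    R <- object$sampling$reduction
    ag <- array(0 + 0i, dim = c(object$n, object$n, object$subspace$rank, R))
    for (j in seq_len(R)) ag[, , , j] <- object$alpha[, , , grp$slices[g, j]]
    y <- hybrid$groups[[g]]
    out$rel_residual[g] <- sqrt(sum(Mod(E$forward(ag) - y)^2) / sum(Mod(y)^2))
  }
  out
}

#' Display reconstructed maps
#'
#' Shows the T1 map, T2 map and match score of one slice as images.
#'
#' @param x an `mrf_recon` fit.
#' @param slice slice to display (default: central).
#' @param ... passed to [graphics::image()].
#' @export
plot.mrf_recon <- function(x, slice = NULL, ...) {
  maps <- x$maps
  nz <- dim(maps$t1_ms)[3]
  if (is.null(slice)) slice <- (nz + 1) %/% 2
  old <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  show <- function(img, main) {
    img[is.na(img)] <- 0
    graphics::image(img, axes = FALSE, main = main,
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  }
  show(maps$t1_ms[, , slice], "T1 (ms)")
  show(maps$t2_ms[, , slice], "T2 (ms)")
  show(maps$match_score[, , slice], "match score")
  invisible(x)
}
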