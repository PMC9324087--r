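#' Non-local means denoising of a coefficient image
#'
#' Replaces every pixel by a weight-normalized average over a centered
#' search window; weights are `exp(-d / h^2)` on mean squared patch
#' differences, and the self-comparison receives the maximum weight
#' observed among the other candidates (the standard treatment; a raw
#' self-weight of one would dominate the average and disable the filter,
#' since two noisy copies of identical structure sit at the noise-floor
#' distance, not at zero).  Complex
#' images are denoised jointly: one weight set is computed from the
#' complex modulus of the patch difference and applied to real and
#' imaginary parts together.  When `strength` is not given, the filter
#' strength is set to `1.5 * sigma_hat`, where `sigma_hat` is a
#' median-absolute-deviation estimate of the per-component noise standard
#' deviation taken from the high-frequency residual of the image (the
#' difference to its 3 x 3 local mean, rescaled for the variance the
#' subtraction adds).
#'
#' @param image complex (or numeric) 2D matrix.
#' @param patch odd patch side in pixels (default 3).
#' @param search search-window side in pixels (default 32); must be at
#'   least `patch`.
#' @param strength filter strength h; defaults to the noise-adaptive value
#'   described above.
#' @return denoised complex matrix of the same size.
#' @export
nlm_denoise <- function(image, patch = 3, search = 32, strength = NULL) {
  patch <- as.integer(patch); search <- as.integer(search)
  if (patch < 1 || patch %% 2 == 0) stop("patch must be odd and >= 1")
  if (search < patch) stop("search window must be at least the patch size")
  if (!is.matrix(image)) stop("image must be a 2D matrix")
  if (!is.complex(image)) storage.mode(image) <- "complex"
  if (is.null(strength)) {
    sig <- estimate_noise_sd(image)
    strength <- 1.5 * max(sig, .Machine$double.eps)
  }
  nlm_cpp(image, patch, search, strength, 0)
}

# MAD estimate of the per-component noise SD from the residual to the
# 3 x 3 local mean; for i.i.d. noise that residual has variance
# sigma^2 * (1 - 1/9) per component, hence the rescaling.
estimate_noise_sd <- function(image) {
  resid <- image - boxmean3(image)
  v <- c(Re(resid), Im(resid))
  stats::mad(v, center = 0) / sqrt(1 - 1 / 9)
}

boxmean3 <- function(img) {
  n1 <- nrow(img); n2 <- ncol(img)
  acc <- matrix(0 + 0i, n1, n2)
  cnt <- matrix(0, n1, n2)
  for (di in -1:1) {
    si <- pmin(pmax(seq_len(n1) + di, 1), n1)
    valid_i <- seq_len(n1) + di >= 1 & seq_len(n1) + di <= n1
    for (dj in -1:1) {
      sj <- pmin(pmax(seq_len(n2) + dj, 1), n2)
      valid_j <- seq_len(n2) + dj >= 1 & seq_len(n2) + dj <= n2
      w <- outer(as.numeric(valid_i), as.numeric(valid_j))
      acc <- acc + img[si, sj] * w
      cnt <- cnt + w
    }
  }
  acc / cnt
}

#' Quantitative parameter maps
#'
#' Container for the end product of the pipeline: voxelwise T1, T2
#' (milliseconds), the complex amplitude M0 of the best-matching unit-
#' normalized dictionary entry, the normalized match score in \[0, 1\], and
#' a validity mask.  Voxels whose score falls below the matching threshold
#' are flagged invalid and carry `NA` relaxation times.
#'
#' @param t1_ms,t2_ms,m0,match_score,valid arrays of identical shape.
#' @param voxel_mm voxel dimensions in millimeters.
#' @return object of class `mrf_maps`.
#' @export
parameter_maps <- function(t1_ms, t2_ms, m0, match_score, valid,
                           voxel_mm = c(1, 1, 1)) {
  stopifnot(identical(dim(t1_ms), dim(t2_ms)),
            identical(dim(t1_ms), dim(match_score)))
  structure(list(t1_ms = t1_ms, t2_ms = t2_ms, m0 = m0,
                 match_score = match_score, valid = valid,
                 voxel_mm = voxel_mm),
            class = "mrf_maps")
}

#' @export
print.mrf_maps <- function(x, ...) {
  d <- dim(x$t1_ms)
  cat("Parameter maps:", paste(d, collapse = " x "), "\n")
  ok <- x$valid
  if (any(ok))
    cat(sprintf("  valid voxels: %d (%.1f%%); T1 %.0f-%.0f ms, T2 %.0f-%.0f ms\n",
                sum(ok), 100 * mean(ok),
                min(x$t1_ms[ok]), max(x$t1_ms[ok]),
                min(x$t2_ms[ok]), max(x$t2_ms[ok])))
  else cat("  no valid voxels\n")
  invisible(x)
}

#' Dot-product dictionary matching
#'
#' Assigns each voxel the (T1, T2) of the dictionary entry maximizing the
#' magnitude of the complex inner product with the voxel signal (phase-
#' insensitive matching against unit-normalized entries; transmit-field
#' variations are ignored).  Matching runs in the K-dimensional compressed
#' domain when a subspace is supplied — the dictionary is projected onto
#' the basis once and voxel coefficients are compared directly, which
#' agrees with full time-domain matching up to the subspace projection
#' error — or in the time domain when `x` carries full-length signals.
#' The search is exhaustive over the grid.
#'
#' @param x coefficient array whose last dimension is K (requires
#'   `subspace`) or signal array whose last dimension is T; a matrix of
#'   voxels x K (or voxels x T) is also accepted.
#' @param dict a normalized [build_dictionary()] result.
#' @param subspace the [compute_subspace()] basis used to form `x`, or
#'   NULL for time-domain matching.
#' @param score_threshold voxels with normalized match score below this
#'   value are flagged invalid rather than assigned (default 0.1).
#' @param voxel_mm voxel dimensions recorded in the result.
#' @return an [parameter_maps()] object; `m0` is the complex amplitude of
#'   the best unit-normalized entry (divide by the entry's stored norm,
#'   `dict$norms`, for a proton-density scale).
#' @export
match_dictionary <- function(x, dict, subspace = NULL, score_threshold = 0.1,
                             voxel_mm = c(1, 1, 1)) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  if (!dict$normalized)
    stop("dictionary must be row-normalized for dot-product matching")
  d <- dim(x)
  if (is.null(d)) stop("x must be an array or matrix")
  nlast <- d[length(d)]
  vox_dim <- d[-length(d)]
  X <- matrix(x, prod(vox_dim), nlast)
  if (!is.complex(X)) storage.mode(X) <- "complex"

  if (!is.null(subspace)) {
    stopifnot(inherits(subspace, "mrf_subspace"))
    if (nlast != subspace$rank)
      stop("last dimension of x must equal the subspace rank")
    # project the dictionary onto the basis and renormalize the compressed
    # rows, so that coefficients synthesized from an entry match it with
    # score exactly 1 regardless of the entry's projection error
    Dc <- Conj(dict$signals) %*% subspace$basis   # n_entries x K
    dc_norm <- sqrt(rowSums(Mod(Dc)^2))
    dc_norm[dc_norm == 0] <- 1
    Dc <- Dc / dc_norm
  } else {
    if (nlast != ncol(dict$signals))
      stop("last dimension of x must equal the dictionary frame count")
    Dc <- Conj(dict$signals)
    dc_norm <- rep(1, nrow(Dc))
  }

  nvox <- nrow(X)
  nentry <- nrow(Dc)
  best_idx <- integer(nvox)
  best_dot <- complex(nvox)
  chunk <- max(1L, as.integer(2^21 / nentry))  # keep the dot matrix small
  for (s in seq(1L, nvox, by = chunk)) {
    e <- min(s + chunk - 1L, nvox)
    dots <- X[s:e, , drop = FALSE] %*% t(Dc)    # voxels x entries
    a <- Mod(dots)
    idx <- max.col(a, ties.method = "first")
    best_idx[s:e] <- idx
    best_dot[s:e] <- dots[cbind(seq_len(e - s + 1L), idx)]
  }
  norms_x <- sqrt(rowSums(Mod(X)^2))
  score <- ifelse(norms_x > 0, Mod(best_dot) / norms_x, 0)
  valid <- score >= score_threshold & norms_x > 0

  t1 <- dict$grid$entries[best_idx, "t1_ms"]
  t2 <- dict$grid$entries[best_idx, "t2_ms"]
  t1[!valid] <- NA_real_
  t2[!valid] <- NA_real_
  m0 <- best_dot / dc_norm[best_idx]  # amplitude of the unit time-domain entry
  m0[!valid] <- 0 + 0i

  shape <- if (length(vox_dim) > 1) vox_dim else c(vox_dim, 1L)
  parameter_maps(t1_ms = array(t1, vox_dim),
                 t2_ms = array(t2, vox_dim),
                 m0 = array(m0, vox_dim),
                 match_score = array(score, vox_dim),
                 valid = array(valid, vox_dim),
                 voxel_mm = voxel_mm)
}

#' Crop slice-oversampled partitions
#'
#' Stack-of-stars protocols acquire extra kz partitions beyond the
#' prescribed slab to absorb imperfect slab excitation; after
#' reconstruction the central prescribed slab is retained.  An
#' oversampling fraction f reduces Nz partitions to `Nz / (1 + f)` slices
#' (40 to 32 for 25%), cropped symmetrically.
#'
#' @param maps an [parameter_maps()] object whose third dimension is the
#'   slice axis.
#' @param oversampling_fraction fraction f in \[0, 1).
#' @return cropped `mrf_maps`.
#' @export
crop_oversampled_slices <- function(maps, oversampling_fraction) {
  stopifnot(inherits(maps, "mrf_maps"))
  f <- oversampling_fraction
  if (f < 0 || f >= 1) stop("oversampling fraction must lie in [0, 1)")
  if (f == 0) return(maps)
  d <- dim(maps$t1_ms)
  if (length(d) < 3) stop("maps must have a slice dimension to crop")
  nz <- d[3]
  n_out <- nz / (1 + f)
  if (abs(n_out - round(n_out)) > 1e-8)
    stop(sprintf(paste0("oversampling fraction %.3g does not yield an integer ",
                        "slice count from %d partitions; use f = Nz/n_out - 1 ",
                        "for an integer target n_out"), f, nz))
  n_out <- as.integer(round(n_out))
  lo <- (nz - n_out) %/% 2
  keep <- (lo + 1):(lo + n_out)
  crop <- function(a) a[, , keep, drop = FALSE]
  parameter_maps(crop(maps$t1_ms), crop(maps$t2_ms), crop(maps$m0),
                 crop(maps$match_score), crop(maps$valid), maps$voxel_mm)
}

#' Write parameter maps as NIfTI volumes
#'
#' Writes `t1.nii.gz`, `t2.nii.gz`, `m0_mag.nii.gz` and `score.nii.gz`
#' into `dir`, carrying the voxel dimensions of the acquisition.  Invalid
#' voxels are written as zero.
#'
#' @param maps an [parameter_maps()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_maps_nifti <- function(maps, dir) {
  stopifnot(inherits(maps, "mrf_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  zero_na <- function(a) { a[is.na(a)] <- 0; a }
  vols <- list(t1 = zero_na(maps$t1_ms),
               t2 = zero_na(maps$t2_ms),
               m0_mag = Mod(maps$m0),
               score = maps$match_score)
  paths <- character(0)
  for (nm in names(vols)) {
    img <- RNifti::asNifti(vols[[nm]])
    RNifti::pixdim(img) <- maps$voxel_mm
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
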