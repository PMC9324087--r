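#' Multi-coil k-space container
#'
#' Holds the complex samples of a stack-of-stars MRF acquisition together
#' with the sampling pattern that produced them.  The sample array is
#' indexed (readout sample, sampled kz partition, frame, coil); only the
#' partitions prescribed by the sampling pattern are present, in the order
#' given by [frame_kz_indices()].
#'
#' @param samples complex array, dim (readout, Nz/R, T, n_coils).
#' @param sampling an [kt_sampling()] object.
#' @param n image matrix size N.
#' @param noise_sd per-component standard deviation of the additive complex
#'   Gaussian noise, if known (metadata only).
#' @return object of class `mrf_kspace`.
#' @export
mrf_kspace <- function(samples, sampling, n, noise_sd = NULL) {
  stopifnot(inherits(sampling, "mrf_sampling"))
  d <- dim(samples)
  if (length(d) != 4) stop("samples must be a 4-d array")
  nkz <- sampling$n_partitions %/% sampling$reduction
  if (d[1] != sampling$readout_samples || d[2] != nkz ||
      d[3] != sampling$n_frames)
    stop("sample array dimensions do not match the sampling pattern")
  if (!is.complex(samples)) storage.mode(samples) <- "complex"
  structure(list(samples = samples, sampling = sampling,
                 n = as.integer(n), noise_sd = noise_sd),
            class = "mrf_kspace")
}

#' @export
print.mrf_kspace <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("MRF k-space: %d frames x %d kz x %d readout x %d coils (R = %d)\n",
              d[3], d[2], d[1], d[4], x$sampling$reduction))
  invisible(x)
}

#' @rdname mrf_kspace
#' @param kdata an `mrf_kspace` object.
#' @param path file path for the raw-data container (RDS; holds the sample
#'   array, the sampling pattern and the geometry attributes).
#' @export
write_kspace <- function(kdata, path) {
  stopifnot(inherits(kdata, "mrf_kspace"))
  saveRDS(kdata, path)
  invisible(path)
}

#' @rdname mrf_kspace
#' @export
read_kspace <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "mrf_kspace"))
  x
}

#' Frame-by-frame inverse Fourier transform along kz
#'
#' Decodes the uniformly sampled kz subgrid of every frame with a unitary
#' inverse DFT, separating the volume into `Nz / R` independent groups of R
#' aliased slices (see [slice_groups()]).  Two known deterministic phases
#' arise in the decoding: a per-group phase that depends on the frame's kz
#' offset (removed here, so downstream operators see only the CAIPIRINHA
#' phases of [caipi_phase()]) and a fixed per-replicate sign (left to the
#' forward model).  The transform is unitary, so sample energy is
#' preserved.
#'
#' @param kdata an [mrf_kspace()] object.
#' @return object of class `mrf_hybrid`: list with `groups` (list of
#'   (readout * T) x n_coils matrices, rows ordered sample-within-frame
#'   then frame), `sampling`, `n`.
#' @export
hybrid_decode <- function(kdata) {
  stopifnot(inherits(kdata, "mrf_kspace"))
  samp <- kdata$sampling
  Nz <- samp$n_partitions
  R <- samp$reduction
  M <- Nz %/% R
  d <- dim(kdata$samples)
  nread <- d[1]; T_ <- d[3]; ncoil <- d[4]

  # unitary inverse DFT on the length-M subgrid
  m <- seq_len(M) - 1
  g <- seq_len(M) - 1
  Wd <- exp(2i * pi * outer(g, m) / M) / sqrt(M)

  groups <- vector("list", M)
  for (gg in seq_len(M)) groups[[gg]] <- matrix(0 + 0i, nread * T_, ncoil)
  for (t in seq_len(T_)) {
    o <- samp$kz_offset[t]
    chi <- exp(-2i * pi * (o - Nz / 2) * g / Nz)  # per-group decode phase
    rows <- ((t - 1) * nread + 1):(t * nread)
    for (c in seq_len(ncoil)) {
      dec <- kdata$samples[, , t, c] %*% t(Wd)  # nread x M
      dec <- sweep(dec, 2, Conj(chi), `*`)      # strip the decode phase
      for (gg in seq_len(M)) groups[[gg]][rows, c] <- dec[, gg]
    }
  }
  structure(list(groups = groups, sampling = samp, n = kdata$n,
                 n_groups = M), class = "mrf_hybrid")
}

#' Re-encode decoded slice-group data to sampled k-space
#'
#' Exact inverse of [hybrid_decode()]; useful to express a slice-group
#' forward model in the acquired-data domain.
#'
#' @param hybrid an `mrf_hybrid` object.
#' @return an [mrf_kspace()] object.
#' @export
hybrid_encode <- function(hybrid) {
  samp <- hybrid$sampling
  Nz <- samp$n_partitions
  R <- samp$reduction
  M <- Nz %/% R
  T_ <- samp$n_frames
  nread <- samp$readout_samples
  ncoil <- ncol(hybrid$groups[[1]])
  m <- seq_len(M) - 1
  g <- seq_len(M) - 1
  We <- exp(-2i * pi * outer(m, g) / M) / sqrt(M)  # conjugate transpose of decode
  samples <- array(0 + 0i, dim = c(nread, M, T_, ncoil))
  for (t in seq_len(T_)) {
    o <- samp$kz_offset[t]
    chi <- exp(-2i * pi * (o - Nz / 2) * g / Nz)
    rows <- ((t - 1) * nread + 1):(t * nread)
    for (c in seq_len(ncoil)) {
      dec <- vapply(seq_len(M), function(gg) hybrid$groups[[gg]][rows, c],
                    complex(nread))
      dec <- sweep(matrix(dec, nread, M), 2, chi, `*`)
      samples[, , t, c] <- dec %*% t(We)
    }
  }
  mrf_kspace(samples, samp, n = hybrid$n)
}

#' Coil sensitivity container
#'
#' @param maps complex array, dim (N, N, Nz, n_coils).
#' @param normalized whether the maps are unit sum-of-squares normalized on
#'   the support.
#' @return object of class `mrf_coils`.
#' @export
mrf_coils <- function(maps, normalized = TRUE) {
  d <- dim(maps)
  if (length(d) != 4) stop("coil maps must be a 4-d array (N, N, Nz, coils)")
  if (any(!is.finite(Re(maps))) || any(!is.finite(Im(maps))))
    stop("coil maps must be finite")
  if (!is.complex(maps)) storage.mode(maps) <- "complex"
  structure(list(maps = maps, normalized = normalized), class = "mrf_coils")
}

#' @export
print.mrf_coils <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("Coil sensitivities: %d coils, %d x %d x %d\n", d[4], d[1], d[2], d[3]))
  invisible(x)
}

#' Subspace forward model for one aliased slice group
#'
#' Assembles the linear operator of the subspace-constrained inverse
#' problem for a single group of R aliased slices: coefficient images are
#' multiplied by the coil sensitivities of the group's true slices,
#' expanded to frames through the temporal basis, evaluated on every
#' frame's radial spoke by the fused gridding operator, modulated by the
#' CAIPIRINHA phases (including the fixed replicate signs and the 1/sqrt(R)
#' decoding scale), and summed over the aliased replicates.  The adjoint is
#' the exact conjugate transpose.
#'
#' @param subspace an [compute_subspace()] result.
#' @param coils an [mrf_coils()] object (full volume).
#' @param sampling an [kt_sampling()] object.
#' @param group 1-based slice-group index.
#' @param fused optionally a precomputed [combine_gridding_with_subspace()]
#'   operator (shared across groups and reconstructions).
#' @return list with functions `forward(alpha)` (alpha array
#'   (N, N, K, R) to a (readout * T) x n_coils matrix), `adjoint(y)` and
#'   `normal(alpha)`, plus the dimensions.
#' @export
subspace_operator <- function(subspace, coils, sampling, group = 1,
                              fused = NULL) {
  stopifnot(inherits(subspace, "mrf_subspace"), inherits(coils, "mrf_coils"),
            inherits(sampling, "mrf_sampling"))
  n <- dim(coils$maps)[1]
  ncoil <- dim(coils$maps)[4]
  if (is.null(fused))
    fused <- combine_gridding_with_subspace(subspace, sampling, n)
  grp <- slice_groups(sampling)
  if (group < 1 || group > grp$n_groups) stop("slice group out of range")
  R <- sampling$reduction
  K <- subspace$rank
  slices <- grp$slices[group, ]
  nread <- sampling$readout_samples
  T_ <- sampling$n_frames
  Mrows <- nread * T_

  # per-frame, per-replicate modulation: CAIPI phase * replicate sign / sqrt(R)
  W <- caipi_phase(sampling) * rep(grp$signs, each = T_) / sqrt(R)
  W_exp <- W[rep(seq_len(T_), each = nread), , drop = FALSE]

  cmaps <- lapply(seq_len(R), function(j) coils$maps[, , slices[j], , drop = FALSE])

  forward <- function(alpha) {
    stopifnot(all(dim(alpha) == c(n, n, K, R)))
    if (any(!is.finite(Re(alpha)))) stop("non-finite input to forward model")
    y <- matrix(0 + 0i, Mrows, ncoil)
    for (j in seq_len(R)) {
      aj <- alpha[, , , j, drop = FALSE]
      dim(aj) <- c(n, n, K)
      for (c in seq_len(ncoil)) {
        kimgs <- aj * as.vector(cmaps[[j]][, , 1, c])
        y[, c] <- y[, c] + W_exp[, j] * fused$forward(kimgs)
      }
    }
    y
  }

  adjoint <- function(y) {
    y <- if (is.matrix(y)) y else matrix(y, ncol = 1)
    stopifnot(nrow(y) == Mrows, ncol(y) == ncoil)
    alpha <- array(0 + 0i, dim = c(n, n, K, R))
    for (j in seq_len(R)) {
      acc <- array(0 + 0i, dim = c(n, n, K))
      for (c in seq_len(ncoil)) {
        w <- Conj(W_exp[, j]) * y[, c]
        imgs <- fused$adjoint(w)
        acc <- acc + imgs * as.vector(Conj(cmaps[[j]][, , 1, c]))
      }
      alpha[, , , j] <- acc
    }
    alpha
  }

  list(forward = forward,
       adjoint = adjoint,
       normal = function(alpha) adjoint(forward(alpha)),
       n = n, rank = K, n_replicates = R, n_coils = ncoil,
       slices = slices, n_rows = Mrows, fused = fused)
}

#' Estimate coil sensitivity maps
#'
#' A rank-one calibration: per-coil images are normalized by the square
#' root of their sum-of-squares, which recovers the sensitivities up to a
#' common per-pixel phase (the leading eigenvector of the pixelwise coil
#' covariance for noiseless data).  Optional image-domain smoothing
#' regularizes the estimate where the object support is weak.  In
#' simulated-mode pipelines the generator's ground-truth maps can be passed
#' through unchanged with `bypass`.
#'
#' @param calib complex array of per-coil calibration images, dim
#'   (N, N, n_coils) for a single slice or (N, N, Nz, n_coils).
#' @param bypass an [mrf_coils()] object to pass through unchanged
#'   (ground-truth mode for simulated data).
#' @param smooth_sigma standard deviation (pixels) of an isotropic Gaussian
#'   smoothing of the calibration images before normalization; 0 disables.
#' @return an [mrf_coils()] object, unit sum-of-squares on the support.
#' @export
estimate_sensitivities <- function(calib = NULL, bypass = NULL, smooth_sigma = 2) {
  if (!is.null(bypass)) {
    stopifnot(inherits(bypass, "mrf_coils"))
    return(bypass)
  }
  if (is.null(calib)) stop("either calibration images or bypass maps are required")
  d <- dim(calib)
  if (length(d) == 3) {
    calib <- array(calib, dim = c(d[1], d[2], 1, d[3]))
    d <- dim(calib)
  }
  if (length(d) != 4) stop("calibration array must be (N, N, [Nz,] coils)")
  n <- d[1]; nz <- d[3]; ncoil <- d[4]
  maps <- array(0 + 0i, dim = d)
  for (z in seq_len(nz)) {
    imgs <- calib[, , z, , drop = TRUE]
    dim(imgs) <- c(n, d[2], ncoil)
    if (smooth_sigma > 0)
      for (c in seq_len(ncoil)) imgs[, , c] <- gauss_smooth2(imgs[, , c], smooth_sigma)
    sos <- sqrt(apply(Mod(imgs)^2, c(1, 2), sum))
    sos[sos == 0] <- 1
    for (c in seq_len(ncoil)) maps[, , z, c] <- imgs[, , c] / sos
  }
  mrf_coils(maps, normalized = TRUE)
}

#' Low-resolution calibration images from an acquisition
#'
#' Computes per-coil, per-slice images for sensitivity calibration by a
#' density-compensated adjoint gridding of the spoke data (a ramp filter,
#' used only for this preview — never inside the forward model), after
#' restricting k-space to a central low-pass window.  Contrast over the
#' train is averaged out, which is harmless for sensitivity estimation.
#'
#' @param kdata a fully partition-encoded (R = 1) [mrf_kspace()] object.
#' @param lowpass_frac radius of the retained central k-space disk in
#'   units of the maximum sampled radius.
#' @return complex array (N, N, Nz, n_coils) of calibration images.
#' @export
calibration_images <- function(kdata, lowpass_frac = 0.25) {
  stopifnot(inherits(kdata, "mrf_kspace"))
  samp <- kdata$sampling
  if (samp$reduction != 1)
    stop("calibration needs a fully partition-encoded (R = 1) acquisition")
  n <- kdata$n
  hy <- hybrid_decode(kdata)
  grp <- slice_groups(samp)
  coords <- all_spoke_coordinates(samp)
  plan <- nufft_plan(coords, n)
  r <- sqrt(rowSums(coords^2))
  w <- r / max(r)                       # ramp density compensation
  w[r > lowpass_frac * max(r)] <- 0     # central low-pass window
  ncoil <- ncol(hy$groups[[1]])
  out <- array(0 + 0i, dim = c(n, n, samp$n_partitions, ncoil))
  for (g in seq_len(grp$n_groups)) {
    z <- grp$slices[g, 1]
    imgs <- nufft_adjoint(plan, hy$groups[[g]] * w)
    out[, , z, ] <- array(imgs, dim = c(n, n, ncoil))
  }
  out
}

#' Export coil maps as NIfTI volumes
#'
#' Writes the complex sensitivities split into magnitude/phase pairs, one
#' file pair per coil.
#'
#' @param coils an [mrf_coils()] object.
#' @param dir output directory.
#' @param voxel_mm voxel dimensions recorded in the headers.
#' @return invisibly, the written paths.
#' @export
write_coils_nifti <- function(coils, dir, voxel_mm = c(1, 1, 1)) {
  stopifnot(inherits(coils, "mrf_coils"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ncoil <- dim(coils$maps)[4]
  paths <- character(0)
  for (c in seq_len(ncoil)) {
    for (part in c("mag", "phase")) {
      vol <- if (part == "mag") Mod(coils$maps[, , , c, drop = TRUE])
             else Arg(coils$maps[, , , c, drop = TRUE])
      img <- RNifti::asNifti(array(vol, dim = dim(coils$maps)[1:3]))
      RNifti::pixdim(img) <- voxel_mm
      p <- file.path(dir, sprintf("coil%02d_%s.nii.gz", c, part))
      RNifti::writeNifti(img, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

# periodic Gaussian smoothing via the FFT
gauss_smooth2 <- function(img, sigma) {
  n1 <- nrow(img); n2 <- ncol(img)
  f1 <- c(0:(n1 %/% 2), -((n1 - n1 %/% 2 - 1):1)) / n1
  f2 <- c(0:(n2 %/% 2), -((n2 - n2 %/% 2 - 1):1)) / n2
  H <- outer(exp(-2 * pi^2 * sigma^2 * f1^2), exp(-2 * pi^2 * sigma^2 * f2^2))
  stats::fft(stats::fft(img) * H, inverse = TRUE) / (n1 * n2)
}
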