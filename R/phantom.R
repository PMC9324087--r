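#' Digital sphere phantom specification
#'
#' Defines a 3D phantom as a set of spheres with assigned relaxation times
#' and proton density on a regular voxel grid, in the spirit of the
#' NiCl2 contrast plate of the NIST/ISMRM system phantom.  Coordinates are
#' in millimeters relative to the grid center.
#'
#' @param n in-plane matrix size N.
#' @param nz number of slices.
#' @param voxel_mm voxel size (dx, dy, dz) in mm.
#' @param spheres data frame with columns `cx, cy, cz` (center, mm),
#'   `radius_mm`, `t1_ms`, `t2_ms`, `m0`.
#' @param background optional list/vector (t1_ms, t2_ms, m0) filling the
#'   non-sphere volume; NULL leaves it empty (signal-free).
#' @param seed RNG seed recorded with the spec (used by the acquisition
#'   simulator's noise draw).
#' @return object of class `mrf_phantom_spec`.
#' @export
phantom_spec <- function(n = 64, nz = 8, voxel_mm = c(3.28, 3.28, 5),
                         spheres, background = NULL, seed = 1L) {
  stopifnot(is.data.frame(spheres),
            all(c("cx", "cy", "cz", "radius_mm", "t1_ms", "t2_ms", "m0")
                %in% names(spheres)))
  if (any(spheres$t2_ms <= 0) || any(spheres$t1_ms < spheres$t2_ms))
    stop("sphere relaxation times must satisfy t1 >= t2 > 0")
  half <- c(n, n, nz) * voxel_mm / 2
  if (any(abs(spheres$cx) + spheres$radius_mm > half[1]) ||
      any(abs(spheres$cy) + spheres$radius_mm > half[2]) ||
      any(abs(spheres$cz) + spheres$radius_mm > half[3]))
    stop("spheres must lie within the grid")
  structure(list(n = as.integer(n), nz = as.integer(nz),
                 voxel_mm = voxel_mm, spheres = spheres,
                 background = background, seed = as.integer(seed)),
            class = "mrf_phantom_spec")
}

#' @export
print.mrf_phantom_spec <- function(x, ...) {
  cat(sprintf("Digital phantom: %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d spheres\n",
              x$n, x$n, x$nz, x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
              nrow(x$spheres)))
  invisible(x)
}

#' Default ten-sphere phantom
#'
#' A documented desk-scale layout: ten spheres of 14 mm radius arranged on
#' a 70 mm circle in a 64 x 64 x 8 volume (3.28 x 3.28 x 5 mm voxels),
#' with T1 from 100-2500 ms and T2 from 20-800 ms.  Every (T1, T2) pair is
#' snapped to the default dictionary grid so that noiseless end-to-end
#' matching can be exact; all pairs are physical (T2 <= T1).
#'
#' @param grid the [dictionary_grid()] whose values the sphere relaxation
#'   times are snapped to (default grid).
#' @param n,nz,voxel_mm grid geometry; the sphere layout scales with the
#'   field of view (circle radius FOV/3, sphere radius FOV/15 capped at
#'   45% of the slab thickness), so the same layout works at the paper
#'   scale (128 x 128 x 40).
#' @param seed RNG seed stored in the spec.
#' @return an [phantom_spec()] object.
#' @export
make_default_phantom <- function(grid = dictionary_grid(), seed = 1L,
                                 n = 64, nz = 8,
                                 voxel_mm = c(3.28, 3.28, 5)) {
  snap <- function(x, values) values[vapply(x, function(v)
    which.min(abs(log(values) - log(v))), integer(1))]
  t1_target <- c(100, 180, 300, 450, 650, 900, 1200, 1600, 2000, 2500)
  t2_target <- c(20, 35, 60, 90, 140, 200, 300, 450, 600, 800)
  t1 <- snap(t1_target, grid$t1_values_ms)
  t2 <- snap(t2_target, grid$t2_values_ms)
  t2 <- pmin(t2, t1)  # physical by construction; kept as a guard
  fov <- n * voxel_mm[1]
  slab <- nz * voxel_mm[3]
  radius <- min(fov / 15, 0.45 * slab)
  ang <- 2 * pi * (seq_len(10) - 1) / 10
  spheres <- data.frame(cx = fov / 3 * cos(ang), cy = fov / 3 * sin(ang),
                        cz = 0, radius_mm = radius,
                        t1_ms = t1, t2_ms = t2, m0 = 1)
  phantom_spec(n = n, nz = nz, voxel_mm = voxel_mm,
               spheres = spheres, background = NULL, seed = seed)
}

#' Rasterize a phantom
#'
#' Produces ground-truth voxel volumes by a center-of-voxel membership
#' test.  Overlapping spheres resolve to the last listed (with a warning).
#'
#' @param spec an [phantom_spec()] object.
#' @return list with arrays `t1_ms`, `t2_ms`, `m0` (N x N x Nz) and
#'   `label` (0 = background/empty, i = i-th sphere).
#' @export
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "mrf_phantom_spec"))
  n <- spec$n; nz <- spec$nz; vx <- spec$voxel_mm
  cx <- ((seq_len(n) - 1) - n / 2 + 0.5) * vx[1]
  cy <- ((seq_len(n) - 1) - n / 2 + 0.5) * vx[2]
  cz <- ((seq_len(nz) - 1) - nz / 2 + 0.5) * vx[3]
  t1 <- array(0, dim = c(n, n, nz))
  t2 <- array(0, dim = c(n, n, nz))
  m0 <- array(0, dim = c(n, n, nz))
  label <- array(0L, dim = c(n, n, nz))
  if (!is.null(spec$background)) {
    bg <- spec$background
    t1[] <- bg[[1]]; t2[] <- bg[[2]]; m0[] <- bg[[3]]
  }
  overlap <- FALSE
  for (i in seq_len(nrow(spec$spheres))) {
    s <- spec$spheres[i, ]
    dx2 <- (cx - s$cx)^2
    dy2 <- (cy - s$cy)^2
    dz2 <- (cz - s$cz)^2
    for (z in seq_len(nz)) {
      if (dz2[z] > s$radius_mm^2) next
      inside <- outer(dx2, dy2, `+`) + dz2[z] <= s$radius_mm^2
      if (any(inside & label[, , z] > 0)) overlap <- TRUE
      t1[, , z][inside] <- s$t1_ms
      t2[, , z][inside] <- s$t2_ms
      m0[, , z][inside] <- s$m0
      label[, , z][inside] <- i
    }
  }
  if (overlap) warning("overlapping spheres: last listed wins")
  list(t1_ms = t1, t2_ms = t2, m0 = m0, label = label,
       voxel_mm = vx, spec = spec)
}

#' Interior sphere voxels
#'
#' Erodes the label volume by one voxel (6-neighborhood): a voxel is
#' interior when all face neighbors carry the same sphere label.  Used to
#' exclude partial-volume edge voxels from region statistics.
#'
#' @param truth a [rasterize_phantom()] result.
#' @return integer label array with non-interior voxels set to 0.
#' @export
interior_labels <- function(truth) {
  lab <- truth$label
  d <- dim(lab)
  interior <- lab > 0
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(nrow(shifts))) {
    sh <- shifts[s, ]
    idx1 <- pmin(pmax(seq_len(d[1]) + sh[1], 1), d[1])
    idx2 <- pmin(pmax(seq_len(d[2]) + sh[2], 1), d[2])
    idx3 <- pmin(pmax(seq_len(d[3]) + sh[3], 1), d[3])
    same <- lab == lab[idx1, idx2, idx3]
    # clamped edges compare a voxel with itself; treat volume borders as exterior
    border <- array(FALSE, d)
    if (sh[1] == 1) border[d[1], , ] <- TRUE
    if (sh[1] == -1) border[1, , ] <- TRUE
    if (sh[2] == 1) border[, d[2], ] <- TRUE
    if (sh[2] == -1) border[, 1, ] <- TRUE
    if (sh[3] == 1) border[, , d[3]] <- TRUE
    if (sh[3] == -1) border[, , 1] <- TRUE
    interior <- interior & same & !border
  }
  out <- lab
  out[!interior] <- 0L
  out
}

#' Simulate smooth coil sensitivities
#'
#' Gaussian-lobed magnitude profiles centered on `n_coils` positions
#' arranged on a spiral around and along the imaging volume — successive
#' coils advance in azimuth and are staggered along the slice direction,
#' as in the multi-row torso arrays the generator stands in for — with a
#' mild linear phase per coil.  The through-plane stagger is essential for
#' a realistic array: it provides the slice-direction sensitivity
#' variation that parallel-imaging reconstructions rely on to separate
#' aliased slices.  Maps are normalized to unit sum-of-squares everywhere;
#' their in-plane construction is periodic (wrapped Gaussian distances,
#' integer-cycle phases), keeping each slice's map band-limited and
#' smooth.
#'
#' @param n_coils number of coils (>= 1).
#' @param n in-plane matrix size.
#' @param nz number of slices.
#' @param fwhm_frac in-plane Gaussian lobe FWHM as a fraction of the FOV.
#' @param z_fwhm_frac through-plane lobe FWHM as a fraction of the slab.
#' @return an [mrf_coils()] object, dim (N, N, Nz, n_coils).
#' @export
simulate_coils <- function(n_coils, n, nz = 1, fwhm_frac = 0.9,
                           z_fwhm_frac = 0.8) {
  n_coils <- as.integer(n_coils)
  if (n_coils < 1) stop("n_coils must be >= 1")
  x <- ((seq_len(n) - 1) - n / 2 + 0.5) / n   # centered, FOV units
  zx <- ((seq_len(nz) - 1) - nz / 2 + 0.5) / max(nz, 1)  # slab units
  maps <- array(0 + 0i, dim = c(n, n, nz, n_coils))
  if (n_coils == 1) {
    maps[] <- 1 + 0i
    return(mrf_coils(maps, normalized = TRUE))
  }
  sigma <- fwhm_frac / 2.355
  sigma_z <- z_fwhm_frac / 2.355
  # wrapped (periodic) squared distance keeps the maps free of boundary
  # discontinuities, so their spectra decay like the Gaussian itself
  pdist2 <- function(v, c0) { d <- (v - c0) %% 1; d <- pmin(d, 1 - d); d^2 }
  for (c in seq_len(n_coils)) {
    th <- 2 * pi * (c - 1) / n_coils
    cxy <- 0.35 * c(cos(th), sin(th))
    cz <- ((c - 0.5) / n_coils - 0.5) * 0.9    # staggered along the slab
    r2 <- outer(pdist2(x, cxy[1]), pdist2(x, cxy[2]), `+`)
    mag <- exp(-r2 / (2 * sigma^2))
    # integer-cycle linear phase per coil (periodic across the FOV)
    kx <- round(cos(th)); ky <- round(sin(th))
    phase <- 2 * pi * (kx * outer(x, rep(1, n)) + ky * outer(rep(1, n), x))
    base <- mag * exp(1i * phase)
    for (z in seq_len(nz)) {
      zfac <- exp(-(zx[z] - cz)^2 / (2 * sigma_z^2))
      maps[, , z, c] <- base * zfac
    }
  }
  sos <- sqrt(apply(Mod(maps)^2, c(1, 2, 3), sum))
  for (c in seq_len(n_coils))
    maps[, , , c] <- array(maps[, , , c], dim = dim(sos)) / sos
  mrf_coils(maps, normalized = TRUE)
}

#' Simulate a stack-of-stars MRF acquisition
#'
#' Generates multi-coil k-space data for a phantom: every voxel follows its
#' exact EPG fingerprint (tissue values are not snapped to any dictionary
#' grid), each frame's contrast image is multiplied by the coil maps,
#' evaluated on the frame's radial spoke by the gridding operator, encoded
#' along kz with a unitary DFT at the partitions prescribed by the sampling
#' pattern, and corrupted by additive complex Gaussian noise (`noise_sd`
#' per real/imaginary component).  An accelerated pattern can be simulated
#' prospectively (only the sampled partitions are kept) or produced by
#' retrospective decimation of a full acquisition via
#' [retrospective_undersample()]; at zero noise the two agree sample for
#' sample.
#'
#' @param truth a [rasterize_phantom()] result (or an [phantom_spec()],
#'   which is rasterized first).
#' @param seq an [mrf_sequence()].
#' @param sampling an [kt_sampling()] pattern; its `n_partitions` must
#'   equal the phantom's slice count.
#' @param coils an [mrf_coils()] object matching the geometry.
#' @param noise_sd per-component k-space noise standard deviation.
#' @param seed RNG seed for the noise draw (defaults to the phantom seed).
#' @param oversample,width gridding accuracy parameters.
#' @return an [mrf_kspace()] object.
#' @export
simulate_acquisition <- function(truth, seq, sampling, coils,
                                 noise_sd = 0, seed = NULL,
                                 oversample = 2, width = 8) {
  if (inherits(truth, "mrf_phantom_spec")) truth <- rasterize_phantom(truth)
  stopifnot(inherits(seq, "mrf_sequence"), inherits(sampling, "mrf_sampling"),
            inherits(coils, "mrf_coils"))
  n <- dim(truth$t1_ms)[1]
  nz <- dim(truth$t1_ms)[3]
  if (nz != sampling$n_partitions)
    stop("sampling n_partitions must equal the phantom slice count")
  if (!all(dim(coils$maps)[1:3] == c(n, n, nz)))
    stop("coil map geometry does not match the phantom")
  ncoil <- dim(coils$maps)[4]
  T_ <- sampling$n_frames
  nread <- sampling$readout_samples
  R <- sampling$reduction
  nkz <- nz %/% R

  # unique tissues and their exact fingerprints
  key <- paste(truth$t1_ms, truth$t2_ms)
  present <- truth$m0 != 0 & truth$t2_ms > 0
  ukey <- unique(key[present])
  if (length(ukey) == 0) {
    samples <- array(0 + 0i, dim = c(nread, nkz, T_, ncoil))
  } else {
    first <- match(ukey, key)
    fps <- epg_fingerprints(seq, truth$t1_ms[first], truth$t2_ms[first])

    plan <- nufft_plan(all_spoke_coordinates(sampling), n,
                       oversample = oversample, width = width)
    M <- nread * T_
    # fingerprints expanded to the stacked (sample-within-frame, frame) rows
    fexp <- t(fps)[rep(seq_len(T_), each = nread), , drop = FALSE]

    # per-slice, per-coil spoke data: sum over tissues of fingerprint[t] *
    # (spoke transform of the tissue mask times M0 times the coil map)
    A <- array(0 + 0i, dim = c(M, ncoil, nz))
    for (z in seq_len(nz)) {
      masks <- list()
      for (u in seq_along(ukey)) {
        mk <- (key[seq((z - 1) * n * n + 1, z * n * n)] == ukey[u]) & present[, , z]
        if (!any(mk)) next
        masks[[length(masks) + 1L]] <- list(u = u, img = truth$m0[, , z] * mk)
      }
      if (length(masks) == 0) next
      for (c in seq_len(ncoil)) {
        stack <- vapply(masks, function(mm)
          as.vector(mm$img * coils$maps[, , z, c]), complex(n * n))
        V <- nufft_forward(plan, matrix(stack, n * n, length(masks)))
        V <- if (is.matrix(V)) V else matrix(V, ncol = 1)
        uvec <- vapply(masks, function(mm) mm$u, integer(1))
        A[, c, z] <- rowSums(V * fexp[, uvec, drop = FALSE])
      }
    }

    # unitary kz encoding at the sampled partitions of each frame
    zc <- (seq_len(nz) - 1) - nz / 2            # centered slice coordinate
    samples <- array(0 + 0i, dim = c(nread, nkz, T_, ncoil))
    for (t in seq_len(T_)) {
      kzs <- frame_kz_indices(sampling, t)      # 0-based partition indices
      kappa <- kzs - nz / 2
      Wz <- exp(-2i * pi * outer(kappa, zc) / nz) / sqrt(nz)  # nkz x nz
      rows <- ((t - 1) * nread + 1):(t * nread)
      for (c in seq_len(ncoil)) {
        samples[, , t, c] <- A[rows, c, ] %*% t(Wz)
      }
    }
  }

  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd > 0) {
    if (is.null(seed)) seed <- truth$spec$seed
    set.seed(seed)
    nel <- length(samples)
    samples <- samples + complex(real = stats::rnorm(nel, 0, noise_sd),
                                 imaginary = stats::rnorm(nel, 0, noise_sd))
  }
  mrf_kspace(samples, sampling, n = n, noise_sd = noise_sd)
}

#' Retrospectively undersample a fully encoded acquisition
#'
#' Decimates an R = 1 stack-of-stars data set to the k-t pattern of a
#' higher reduction factor by keeping, in each frame, only the partitions
#' the accelerated pattern prescribes.  At zero noise this reproduces the
#' prospectively simulated accelerated data exactly.
#'
#' @param kdata an R = 1 [mrf_kspace()] object.
#' @param reduction target reduction factor R.
#' @param kz_cycle_origin offset of the kz alternation (see
#'   [kt_sampling()]).
#' @return an [mrf_kspace()] object with the accelerated sampling pattern.
#' @export
retrospective_undersample <- function(kdata, reduction, kz_cycle_origin = 0) {
  stopifnot(inherits(kdata, "mrf_kspace"))
  samp <- kdata$sampling
  if (samp$reduction != 1)
    stop("retrospective undersampling starts from an R = 1 acquisition")
  new_samp <- kt_sampling(samp$n_frames, samp$n_partitions,
                          reduction = reduction,
                          angle_increment_rad = samp$angle_increment_rad,
                          seed_angle_rad = samp$seed_angle_rad,
                          readout_samples = samp$readout_samples,
                          kz_cycle_origin = kz_cycle_origin)
  nkz <- samp$n_partitions %/% reduction
  d <- dim(kdata$samples)
  out <- array(0 + 0i, dim = c(d[1], nkz, d[3], d[4]))
  for (t in seq_len(d[3])) {
    keep <- frame_kz_indices(new_samp, t) + 1L   # 1-based partition columns
    out[, , t, ] <- kdata$samples[, keep, t, ]
  }
  mrf_kspace(out, new_samp, n = kdata$n, noise_sd = kdata$noise_sd)
}

#' Noise level for a target k-space SNR
#'
#' Per-component Gaussian standard deviation giving a k-space
#' signal-to-noise ratio of `snr`, defined as the ratio of the RMS sample
#' magnitude of the noiseless data to the RMS complex noise magnitude
#' (`sd * sqrt(2)` per sample).
#'
#' @param kdata a noiseless [mrf_kspace()] object.
#' @param snr target SNR.
#' @export
noise_sd_for_snr <- function(kdata, snr = 30) {
  stopifnot(inherits(kdata, "mrf_kspace"))
  rms <- sqrt(mean(Mod(kdata$samples)^2))
  rms / (snr * sqrt(2))
}
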