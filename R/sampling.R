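#' Tiny golden angle
#'
#' The n-th tiny golden angle, `pi / (tau + n - 1)` radians with `tau` the
#' golden ratio.  The default used throughout the package is the 7th,
#' about 23.628 degrees, a standard increment for radial acquisitions that
#' need near-uniform angular coverage over short windows.
#'
#' @param n index of the tiny golden angle (n = 1 gives the full golden
#'   angle pi/tau).
#' @export
tiny_golden_angle <- function(n = 7) {
  tau <- (1 + sqrt(5)) / 2
  pi / (tau + n - 1)
}

#' k-t sampling pattern for stack-of-stars MRF
#'
#' Generates the joint (spoke angle, kz partition) sampling schedule.  Each
#' MRF frame acquires a single unique in-plane spoke angle, incremented by
#' a constant (tiny golden-angle) step.  Along the partition direction a
#' uniform subset of `n_partitions / reduction` kz indices is sampled per
#' frame; the subset offset cycles through `0 .. R-1` with the frame index,
#' so for R = 2 the phase-encoding index alternates between the even and
#' odd partitions from frame to frame.  For R = 1 every partition is
#' sampled at the frame's angle.
#'
#' @param n_frames number of MRF frames T.
#' @param n_partitions number of kz partitions Nz; must be divisible by
#'   `reduction`.
#' @param reduction through-plane acceleration factor R (integer >= 1).
#' @param angle_increment_rad spoke-angle increment per frame; default the
#'   7th tiny golden angle.
#' @param seed_angle_rad angle of frame 1.
#' @param readout_samples samples per spoke (default 128).
#' @param kz_cycle_origin offset of the R-periodic kz cycle: frame t
#'   (0-based) samples partitions `{((t + origin) mod R) + m R}`.
#' @return object of class `mrf_sampling` with per-frame `spoke_angle_rad`
#'   and `kz_offset` (the first sampled partition index of each frame).
#' @export
kt_sampling <- function(n_frames, n_partitions, reduction = 1,
                        angle_increment_rad = tiny_golden_angle(7),
                        seed_angle_rad = 0,
                        readout_samples = 128,
                        kz_cycle_origin = 0) {
  n_frames <- as.integer(n_frames)
  n_partitions <- as.integer(n_partitions)
  reduction <- as.integer(reduction)
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (reduction < 1) stop("reduction must be >= 1")
  if (n_partitions %% reduction != 0)
    stop("reduction must divide n_partitions")
  t0 <- seq_len(n_frames) - 1L
  structure(list(n_frames = n_frames,
                 n_partitions = n_partitions,
                 reduction = reduction,
                 spoke_angle_rad = (seed_angle_rad + t0 * angle_increment_rad) %% (2 * pi),
                 kz_offset = (t0 + as.integer(kz_cycle_origin)) %% reduction,
                 angle_increment_rad = angle_increment_rad,
                 seed_angle_rad = seed_angle_rad,
                 readout_samples = as.integer(readout_samples),
                 kz_cycle_origin = as.integer(kz_cycle_origin)),
            class = "mrf_sampling")
}

#' @export
print.mrf_sampling <- function(x, ...) {
  cat(sprintf("k-t sampling: %d frames, Nz = %d, R = %d, %d samples/spoke\n",
              x$n_frames, x$n_partitions, x$reduction, x$readout_samples))
  cat(sprintf("  angle increment %.4f rad (%.3f deg), seed %.4f rad\n",
              x$angle_increment_rad, x$angle_increment_rad * 180 / pi,
              x$seed_angle_rad))
  invisible(x)
}

#' Partitions sampled by one frame
#'
#' @param sampling an [kt_sampling()] object.
#' @param frame 1-based frame index.
#' @return integer vector of 0-based kz partition indices (partition 0 is
#'   the most negative kz).
#' @export
frame_kz_indices <- function(sampling, frame) {
  stopifnot(inherits(sampling, "mrf_sampling"))
  if (frame < 1 || frame > sampling$n_frames) stop("frame out of range")
  sampling$kz_offset[frame] +
    sampling$reduction * (seq_len(sampling$n_partitions %/% sampling$reduction) - 1L)
}

#' CAIPIRINHA phase modulation
#'
#' The per-frame multiplicative phase seen by each aliased slice replicate
#' after the frame-by-frame inverse Fourier transform along the sampled kz
#' subgrid.  Replicate r (spatial offset `r * Nz / R` partitions along z)
#' at a frame with kz offset `o` carries phase `exp(-2i pi o r / R)` by the
#' Fourier shift theorem; for R = 2 the shifted replicate alternates
#' between +1 and -1 over frames.  Frame-independent phase factors that the
#' decoding transform also introduces (a per-slice-group phase and a fixed
#' replicate sign) are not part of this operator; [hybrid_decode()] removes
#' or book-keeps them so that the forward model sees exactly these phases.
#'
#' @param sampling an [kt_sampling()] object.
#' @return complex T x R matrix of unit-modulus phases.
#' @export
caipi_phase <- function(sampling) {
  stopifnot(inherits(sampling, "mrf_sampling"))
  R <- sampling$reduction
  o <- sampling$kz_offset
  outer(o, seq_len(R) - 1L, function(ot, r) exp(-2i * pi * ot * r / R))
}

#' In-plane spoke coordinates
#'
#' k-space coordinates of one frame's radial spoke: `readout_samples`
#' points linearly spaced along a diameter at the frame's angle, radial
#' coordinate `(s - n/2) / n` for 0-based sample `s`, covering
#' \[-0.5, 0.5) cycles/pixel.  With an even number of samples the k-space
#' origin is sampled exactly (at `s = n/2`).
#'
#' @param sampling an [kt_sampling()] object.
#' @param frame 1-based frame index.
#' @return `readout_samples` x 2 matrix of (kx, ky) in cycles/pixel.
#' @export
spoke_coordinates <- function(sampling, frame) {
  stopifnot(inherits(sampling, "mrf_sampling"))
  if (frame < 1 || frame > sampling$n_frames) stop("frame out of range")
  n <- sampling$readout_samples
  radius <- ((seq_len(n) - 1) - n / 2) / n
  theta <- sampling$spoke_angle_rad[frame]
  cbind(kx = radius * cos(theta), ky = radius * sin(theta))
}

# Stacked (kx, ky) coordinates of all frames, (T * readout) x 2, frame-major
# in the sense that rows are ordered (sample within spoke, then frame).
all_spoke_coordinates <- function(sampling) {
  n <- sampling$readout_samples
  radius <- ((seq_len(n) - 1) - n / 2) / n
  theta <- rep(sampling$spoke_angle_rad, each = n)
  r <- rep(radius, times = sampling$n_frames)
  cbind(kx = r * cos(theta), ky = r * sin(theta))
}

#' Aliased slice groups of a sampling pattern
#'
#' After the per-frame inverse Fourier transform along the sampled kz
#' subgrid, the volume separates into `Nz / R` independent groups of R
#' aliased slices.  Group g (0-based) holds the true slices
#' `(g + Nz/2 + j * Nz/R) mod Nz` for replicate `j = 0 .. R-1` (slice
#' indices 0-based; the half-FOV offset comes from partition 0 being the
#' most negative kz).  Each replicate also carries a fixed sign
#' `(-1)^(j * Nz / R)` that is independent of the frame; the forward model
#' applies it together with the CAIPIRINHA phases.
#'
#' @param sampling an [kt_sampling()] object.
#' @return list with `slices` (n_groups x R matrix of 1-based slice
#'   indices), `signs` (length-R replicate signs) and `n_groups`.
#' @export
slice_groups <- function(sampling) {
  stopifnot(inherits(sampling, "mrf_sampling"))
  Nz <- sampling$n_partitions
  R <- sampling$reduction
  M <- Nz %/% R
  g <- seq_len(M) - 1L
  j <- seq_len(R) - 1L
  slices <- outer(g, j, function(gg, jj) ((gg + Nz %/% 2 + jj * M) %% Nz) + 1L)
  signs <- (-1)^(j * M)
  list(slices = slices, signs = signs, n_groups = M)
}

#' Persist a sampling pattern
#'
#' @param sampling an `mrf_sampling`.
#' @param path file path (RDS container with angles, kz offsets and the
#'   R/Nz/T/increment attributes).
#' @export
write_sampling <- function(sampling, path) {
  stopifnot(inherits(sampling, "mrf_sampling"))
  saveRDS(sampling, path)
  invisible(path)
}

#' @rdname write_sampling
#' @export
read_sampling <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "mrf_sampling"))
  x
}
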