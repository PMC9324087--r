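#' Dictionary grid of (T1, T2) pairs
#'
#' Builds the grid of candidate relaxation-time pairs for dictionary
#' matching.  The cartesian product of the two value lists is filtered to
#' the physical region `t2 <= t1`.  Defaults are logarithmically spaced and
#' bracket both the NiCl2 plate of the NIST/ISMRM system phantom and the
#' tissue ranges seen at low field.
#'
#' @param t1_values_ms ascending T1 values in ms (default 60 points,
#'   log-spaced over 10-3000 ms).
#' @param t2_values_ms ascending T2 values in ms (default 60 points,
#'   log-spaced over 5-1500 ms).
#' @return object of class `mrf_dictionary_grid` with the value lists and an
#'   `entries` matrix (columns `t1_ms`, `t2_ms`).
#' @export
dictionary_grid <- function(t1_values_ms = exp(seq(log(10), log(3000), length.out = 60)),
                            t2_values_ms = exp(seq(log(5), log(1500), length.out = 60))) {
  t1_values_ms <- as.numeric(t1_values_ms)
  t2_values_ms <- as.numeric(t2_values_ms)
  if (any(t1_values_ms <= 0) || any(t2_values_ms <= 0))
    stop("all grid values must be positive")
  if (is.unsorted(t1_values_ms, strictly = TRUE) ||
      is.unsorted(t2_values_ms, strictly = TRUE))
    stop("grid values must be strictly ascending")
  entries <- expand.grid(t2_ms = t2_values_ms, t1_ms = t1_values_ms,
                         KEEP.OUT.ATTRS = FALSE)
  entries <- entries[entries$t2_ms <= entries$t1_ms, c("t1_ms", "t2_ms")]
  entries <- as.matrix(entries)
  rownames(entries) <- NULL
  if (nrow(entries) == 0) stop("grid is empty after the t2 <= t1 filter")
  structure(list(t1_values_ms = t1_values_ms,
                 t2_values_ms = t2_values_ms,
                 entries = entries),
            class = "mrf_dictionary_grid")
}

#' @export
print.mrf_dictionary_grid <- function(x, ...) {
  cat(sprintf("MRF dictionary grid: %d x %d values, %d entries (t2 <= t1)\n",
              length(x$t1_values_ms), length(x$t2_values_ms), nrow(x$entries)))
  cat(sprintf("  T1 %.4g-%.4g ms, T2 %.4g-%.4g ms\n",
              min(x$t1_values_ms), max(x$t1_values_ms),
              min(x$t2_values_ms), max(x$t2_values_ms)))
  invisible(x)
}

#' Build a fingerprint dictionary
#'
#' Simulates one EPG fingerprint per grid entry and (by default) normalizes
#' every row to unit L2 norm, the form required by dot-product matching.
#' No B1+ dimension is simulated: transmit-field variations are ignored by
#' design, matching the reconstruction pipeline this package implements.
#'
#' @param seq an [mrf_sequence()].
#' @param grid an [dictionary_grid()] object.
#' @param normalize normalize rows to unit L2 norm (default `TRUE`).
#' @return object of class `mrf_dictionary` with fields `signals`
#'   (n_entries x T complex), `grid`, `normalized`, `norms` (the pre-
#'   normalization row norms) and `seq`.
#' @export
build_dictionary <- function(seq, grid, normalize = TRUE) {
  stopifnot(inherits(seq, "mrf_sequence"), inherits(grid, "mrf_dictionary_grid"))
  if (nrow(grid$entries) == 0) stop("empty dictionary grid")
  signals <- epg_fingerprints(seq, grid$entries[, "t1_ms"], grid$entries[, "t2_ms"])
  norms <- sqrt(rowSums(Mod(signals)^2))
  if (normalize) {
    if (any(norms == 0)) stop("zero-signal dictionary entry cannot be normalized")
    signals <- signals / norms
  }
  structure(list(signals = signals,
                 grid = grid,
                 normalized = normalize,
                 norms = norms,
                 seq = seq),
            class = "mrf_dictionary")
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf("MRF dictionary: %d entries x %d frames%s\n",
              nrow(x$signals), ncol(x$signals),
              if (x$normalized) ", rows unit-normalized" else ""))
  invisible(x)
}

#' Temporal subspace of a dictionary
#'
#' Computes the rank-`rank` temporal subspace: the leading right singular
#' vectors of the dictionary matrix D (n_entries x T).  All fingerprints
#' are approximately linear combinations of these `rank` temporal modes, so
#' the reconstruction can solve for `rank` coefficient images instead of
#' one image per frame.
#'
#' @param dict an [build_dictionary()] result.
#' @param rank subspace dimension K (default 5).
#' @return object of class `mrf_subspace` with `basis` (T x K, orthonormal
#'   columns) and `rank`.
#' @export
compute_subspace <- function(dict, rank = 5) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  n <- nrow(dict$signals)
  T_ <- ncol(dict$signals)
  rank <- as.integer(rank)
  if (rank < 1 || rank > min(n, T_))
    stop("rank must lie in [1, min(n_entries, T)]")
  sv <- svd(dict$signals, nu = 0, nv = rank)
  # D = U S V^H, so rows of D live in the span of Conj(V):
  # with basis = Conj(V) a time signal s satisfies s ~ basis %*% (basis^H s)
  structure(list(basis = Conj(sv$v[, seq_len(rank), drop = FALSE]),
                 rank = rank,
                 singular_values = sv$d),
            class = "mrf_subspace")
}

#' @export
print.mrf_subspace <- function(x, ...) {
  cat(sprintf("MRF temporal subspace: %d frames, rank %d\n",
              nrow(x$basis), x$rank))
  invisible(x)
}

#' Relative projection residual of a dictionary onto a subspace
#'
#' Returns `||D - D Phi Phi^H||_F / ||D||_F`, the fraction of dictionary
#' energy outside the temporal subspace.
#'
#' @param dict an `mrf_dictionary`.
#' @param subspace an `mrf_subspace`.
#' @export
subspace_residual <- function(dict, subspace) {
  stopifnot(inherits(dict, "mrf_dictionary"), inherits(subspace, "mrf_subspace"))
  D <- dict$signals
  P <- subspace$basis
  proj <- (D %*% Conj(P)) %*% t(P)
  sqrt(sum(Mod(D - proj)^2) / sum(Mod(D)^2))
}

#' Persist a dictionary
#'
#' Dictionaries are stored as a self-describing container (an RDS file
#' holding the complex signal matrix, the grid value lists and the
#' normalization flag), readable with [read_dictionary()].
#'
#' @param dict an `mrf_dictionary`.
#' @param path file path.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  saveRDS(dict, path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  dict <- readRDS(path)
  stopifnot(inherits(dict, "mrf_dictionary"))
  dict
}
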