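#' Per-region statistics of parameter maps
#'
#' Mean and sample standard deviation of the T1 and T2 estimates within
#' each labeled region (e.g. each contrast sphere).  Voxels flagged
#' invalid by the matcher are excluded; regions left with no valid voxels
#' are reported with `n_voxels = 0` and `NA` statistics rather than being
#' dropped.
#'
#' @param maps an [parameter_maps()] object.
#' @param label_volume integer array of region labels (0 = ignore),
#'   aligned with the maps.
#' @return data frame with one row per label: `label`, `n_voxels`,
#'   `t1_mean`, `t1_sd`, `t2_mean`, `t2_sd`.  SDs use the sample (n - 1)
#'   convention.
#' @export
roi_stats <- function(maps, label_volume) {
  stopifnot(inherits(maps, "mrf_maps"))
  if (!identical(dim(maps$t1_ms), dim(label_volume)))
    stop("label volume must align with the maps")
  labels <- sort(unique(label_volume[label_volume > 0]))
  out <- data.frame(label = labels, n_voxels = 0L,
                    t1_mean = NA_real_, t1_sd = NA_real_,
                    t2_mean = NA_real_, t2_sd = NA_real_)
  for (i in seq_along(labels)) {
    sel <- label_volume == labels[i] & maps$valid
    n <- sum(sel)
    out$n_voxels[i] <- n
    if (n >= 1) {
      out$t1_mean[i] <- mean(maps$t1_ms[sel])
      out$t2_mean[i] <- mean(maps$t2_ms[sel])
      out$t1_sd[i] <- if (n >= 2) stats::sd(maps$t1_ms[sel]) else 0
      out$t2_sd[i] <- if (n >= 2) stats::sd(maps$t2_ms[sel]) else 0
    }
  }
  out
}

#' Agreement metrics between two reconstructions
#'
#' Reproduces the standard phantom comparison between an unaccelerated and
#' an accelerated reconstruction: mean absolute percent error of the
#' per-region means (relative to the reference), Pearson correlation of
#' the per-region means, and the mean ratio of the reference to the
#' accelerated per-region standard deviations (a noise-reduction factor).
#'
#' @param stats_ref [roi_stats()] of the reference (e.g. R = 1)
#'   reconstruction.
#' @param stats_acc [roi_stats()] of the accelerated reconstruction; the
#'   label sets must match.
#' @return list with `t1_mae_pct`, `t2_mae_pct`, `t1_cor`, `t2_cor`,
#'   `t1_sd_ratio`, `t2_sd_ratio` and the paired per-region samples
#'   (`pairs`), so that any external statistics package can run formal
#'   tests on them.
#' @export
agreement_metrics <- function(stats_ref, stats_acc) {
  if (!identical(stats_ref$label, stats_acc$label))
    stop("region labels of the two reconstructions do not match")
  ok <- stats_ref$n_voxels > 0 & stats_acc$n_voxels > 0
  r <- stats_ref[ok, ]; a <- stats_acc[ok, ]
  mae <- function(ref, acc) mean(100 * abs(acc - ref) / ref)
  corr <- function(ref, acc)
    if (length(unique(ref)) > 1) stats::cor(ref, acc) else NA_real_
  sd_ratio <- function(ref, acc) {
    sel <- acc > 0
    if (any(sel)) mean(ref[sel] / acc[sel]) else NA_real_
  }
  list(t1_mae_pct = mae(r$t1_mean, a$t1_mean),
       t2_mae_pct = mae(r$t2_mean, a$t2_mean),
       t1_cor = corr(r$t1_mean, a$t1_mean),
       t2_cor = corr(r$t2_mean, a$t2_mean),
       t1_sd_ratio = sd_ratio(r$t1_sd, a$t1_sd),
       t2_sd_ratio = sd_ratio(r$t2_sd, a$t2_sd),
       pairs = data.frame(label = r$label,
                          t1_ref = r$t1_mean, t1_acc = a$t1_mean,
                          t2_ref = r$t2_mean, t2_acc = a$t2_mean,
                          t1_sd_ref = r$t1_sd, t1_sd_acc = a$t1_sd,
                          t2_sd_ref = r$t2_sd, t2_sd_acc = a$t2_sd))
}

#' Pooled voxelwise correlation
#'
#' Pearson correlation of T1 (and T2) over all valid voxels inside the
#' labeled regions of two co-registered maps — the pooled-voxel analysis
#' used for in-vivo style comparisons, complementing the per-region means
#' of [agreement_metrics()].
#'
#' @param maps_ref,maps_acc co-registered [parameter_maps()] objects.
#' @param label_volume region labels (0 = ignore).
#' @return list with `t1_cor`, `t2_cor` and `n_voxels`.
#' @export
pooled_correlation <- function(maps_ref, maps_acc, label_volume) {
  sel <- label_volume > 0 & maps_ref$valid & maps_acc$valid
  n <- sum(sel)
  if (n < 3) return(list(t1_cor = NA_real_, t2_cor = NA_real_, n_voxels = n))
  list(t1_cor = stats::cor(maps_ref$t1_ms[sel], maps_acc$t1_ms[sel]),
       t2_cor = stats::cor(maps_ref$t2_ms[sel], maps_acc$t2_ms[sel]),
       n_voxels = n)
}
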