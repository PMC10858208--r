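#' Dead-cell classification cut-offs
#'
#' Voxels whose dynamics metric falls strictly below the cut-off are counted
#' as dead. Defaults are the empirical values 3 dB^2 (LIV) and 2e-4 1/ms
#' (OCDS_l).
#'
#' @param liv_cutoff LIV cut-off, dB^2.
#' @param ocds_cutoff OCDS_l cut-off, 1/ms.
#' @return A `viability_cutoffs` object.
#' @export
viability_cutoffs <- function(liv_cutoff = 3, ocds_cutoff = 2e-4) {
  structure(list(liv_cutoff = assert_positive(liv_cutoff, "liv_cutoff"),
                 ocds_cutoff = assert_positive(ocds_cutoff, "ocds_cutoff")),
            class = "viability_cutoffs")
}

mask_of <- function(mask) {
  if (is_segmentation_mask(mask)) mask$mask else as.array(mask)
}

#' Spheroid volume from a segmentation mask
#'
#' Voxel count times voxel volume.
#'
#' @param mask A [segment_spheroid()] result (or logical array, with
#'   `voxel_volume_mm3` supplied).
#' @param voxel_volume_mm3 Override for the per-voxel volume.
#' @return Volume in mm^3.
#' @export
compute_volume <- function(mask, voxel_volume_mm3 = NULL) {
  vv <- voxel_volume_mm3 %||%
    (if (is_segmentation_mask(mask)) mask$voxel_volume_mm3 else NULL)
  if (is.null(vv) || is.na(vv)) stop_doct("voxel volume unknown; supply `voxel_volume_mm3`")
  sum(mask_of(mask)) * vv
}

#' Mean dynamics metrics over the segmented spheroid
#'
#' @param mask A [segment_spheroid()] result or logical array.
#' @param liv,ocds `dynamics_volume`s co-registered with the mask.
#' @return A one-row tibble with `mean_liv` (dB^2) and `mean_ocds` (1/ms).
#' @export
mean_metrics <- function(mask, liv, ocds) {
  m <- mask_of(mask)
  stopifnot(is_dynamics_volume(liv), is_dynamics_volume(ocds),
            identical(dim(m), dim(liv$values)),
            identical(dim(m), dim(ocds$values)))
  if (!any(m)) stop_doct("empty segmentation mask")
  tibble(mean_liv = mean(liv$values[m]), mean_ocds = mean(ocds$values[m]))
}

#' Dead-cell ratio of a dynamics metric
#'
#' Fraction of in-mask voxels whose metric value lies strictly below the
#' cut-off for that metric (LIV cut-off for a LIV volume, OCDS_l cut-off for
#' an OCDS_l volume).
#'
#' @param mask A [segment_spheroid()] result or logical array.
#' @param metric A `dynamics_volume`.
#' @param cutoffs A [viability_cutoffs()].
#' @return Ratio in \[0, 1\].
#' @export
dead_cell_ratio <- function(mask, metric, cutoffs = viability_cutoffs()) {
  m <- mask_of(mask)
  stopifnot(is_dynamics_volume(metric), identical(dim(m), dim(metric$values)))
  if (!any(m)) stop_doct("empty segmentation mask")
  cutoff <- switch(metric$metric,
                   LIV = cutoffs$liv_cutoff,
                   OCDS_l = cutoffs$ocds_cutoff,
                   stop_doct("unknown metric '%s'", metric$metric))
  mean(metric$values[m] < cutoff)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value. Two identical constant groups give `t = 0, p = 1`;
#' constant groups with different values give `t = Inf, p = 0`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A one-row tibble with `t`, `dof`, `p`.
#' @examples
#' welch_ttest(c(1, 2, 3), c(2, 4, 6))
#' @export
welch_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_doct("each group needs at least 2 observations")
  }
  if (anyNA(group_a) || anyNA(group_b)) stop_doct("groups must be free of NA")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(tibble(t = 0, dof = NA_real_, p = 1))
    }
    return(tibble(t = sign(mean(group_a) - mean(group_b)) * Inf,
                  dof = NA_real_, p = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  tibble(t = unname(ht$statistic), dof = unname(ht$parameter),
         p = unname(ht$p.value))
}

#' Scalar quantities of one segmented spheroid
#'
#' @param mask A [segment_spheroid()] result.
#' @param liv,ocds `dynamics_volume`s from [compute_dynamics()].
#' @param cutoffs A [viability_cutoffs()].
#' @return A one-row tibble: `volume_mm3`, `mean_liv`, `mean_ocds`,
#'   `dead_ratio_liv`, `dead_ratio_ocds`, `n_voxels`.
#' @export
quantify_spheroid <- function(mask, liv, ocds, cutoffs = viability_cutoffs()) {
  mm <- mean_metrics(mask, liv, ocds)
  tibble(
    volume_mm3 = compute_volume(mask),
    mean_liv = mm$mean_liv,
    mean_ocds = mm$mean_ocds,
    dead_ratio_liv = dead_cell_ratio(mask, liv, cutoffs),
    dead_ratio_ocds = dead_cell_ratio(mask, ocds, cutoffs),
    n_voxels = sum(mask_of(mask))
  )
}
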