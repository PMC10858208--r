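#' Segmentation configuration
#'
#' Automates the usual two-step semi-automatic procedure: an intensity
#' threshold with connected-region selection B-scan by B-scan, followed by
#' removal of the plate-bottom reflection. Both steps accept manual input
#' (a numeric threshold; a user-supplied plate mask) for fidelity with
#' operator-driven workflows.
#'
#' @param intensity_threshold_db Numeric dB threshold, or `"otsu"` for an
#'   automatic threshold on the mean-dB volume.
#' @param min_component_voxels Smallest acceptable spheroid size, voxels.
#' @param closing_radius Radius (voxels) of the per-B-scan morphological
#'   closing applied to the final mask; 0 disables.
#' @param plate_removal `"auto"` (detect the dominant near-horizontal bright
#'   plane and excise a +/-2-voxel slab) or `"none"`.
#' @return A `segmentation_config` object.
#' @export
segmentation_config <- function(intensity_threshold_db = "otsu",
                                min_component_voxels = 27,
                                closing_radius = 1,
                                plate_removal = c("auto", "none")) {
  if (!(identical(intensity_threshold_db, "otsu") ||
        (is.numeric(intensity_threshold_db) && length(intensity_threshold_db) == 1L))) {
    stop_doct("`intensity_threshold_db` must be a number or \"otsu\"")
  }
  structure(
    list(intensity_threshold_db = intensity_threshold_db,
         min_component_voxels = assert_count(min_component_voxels,
                                             "min_component_voxels"),
         closing_radius = assert_count(closing_radius, "closing_radius", min = 0L),
         plate_removal = match.arg(plate_removal)),
    class = "segmentation_config"
  )
}

is_segmentation_config <- function(x) inherits(x, "segmentation_config")

otsu_threshold_db <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop_doct("cannot threshold a constant volume")
  norm <- matrix((as.vector(x) - lo) / (hi - lo), ncol = 1L)
  t01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256L)
  lo + t01 * (hi - lo)
}

# Detect the plate plane: a depth row where the thresholded mask covers
# nearly the full lateral extent. Returns the depth index or NA.
detect_plate_depth <- function(bin, mean_db, min_coverage = 0.8) {
  frac <- apply(bin, 2, mean)
  cand <- which(frac >= min_coverage)
  if (length(cand) == 0L) return(NA_integer_)
  row_med <- vapply(cand, function(d) stats::median(mean_db[, d, ]), numeric(1))
  cand[which.max(row_med)]
}

# Largest 4-connected region per B-scan slice (depth x lateral).
largest_region_2d <- function(slice) {
  lab <- EBImage::bwlabel(slice)
  n <- max(lab)
  if (n == 0L) return(slice & FALSE)
  if (n == 1L) return(lab == 1L)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  lab == which.max(sizes)
}

# After per-slice reduction each slice holds at most one region; 3D
# components are runs of consecutive slices whose regions overlap.
largest_component_3d <- function(mask) {
  L <- dim(mask)[1]
  comp <- integer(L)
  n_comp <- 0L
  for (i in seq_len(L)) {
    if (!any(mask[i, , ])) next
    if (i > 1L && comp[i - 1L] > 0L && any(mask[i, , ] & mask[i - 1L, , ])) {
      comp[i] <- comp[i - 1L]
    } else {
      n_comp <- n_comp + 1L
      comp[i] <- n_comp
    }
  }
  if (n_comp == 0L) return(mask)
  sizes <- vapply(seq_len(n_comp), function(cid) {
    sum(mask[comp == cid, , , drop = FALSE])
  }, numeric(1))
  keep <- which.max(sizes)
  mask[comp != keep & comp != 0L, , ] <- FALSE
  mask
}

#' Segment spheroid tissue from a mean-intensity volume
#'
#' Pipeline: dB threshold (numeric or Otsu) -> plate-plane excision (auto
#' detection of the dominant bright near-horizontal plane, or a supplied
#' mask) -> per-B-scan largest connected region -> largest 3D component ->
#' per-B-scan morphological closing (plate slab re-excised afterwards so the
#' mask never touches it).
#'
#' @param mean_intensity_db 3D array `[location, depth, lateral]` of mean dB
#'   intensity, or a `dynamics_volume` (its `mean_intensity_db` is used).
#' @param cfg A [segmentation_config()].
#' @param protocol A [scan_protocol()] for the voxel volume; taken from a
#'   `dynamics_volume` input when omitted.
#' @param plate_mask Optional logical 3D array of voxels to excise instead of
#'   auto detection.
#' @return A `segmentation_mask`: list with `mask` (logical 3D array),
#'   `voxel_volume_mm3`, `threshold_db`, `plate_depth` (NA if none found) and
#'   `config`.
#' @export
segment_spheroid <- function(mean_intensity_db, cfg = segmentation_config(),
                             protocol = NULL, plate_mask = NULL) {
  stopifnot(is_segmentation_config(cfg))
  if (is_dynamics_volume(mean_intensity_db)) {
    protocol <- protocol %||% mean_intensity_db$protocol
    mean_intensity_db <- mean_intensity_db$mean_intensity_db
  }
  stopifnot(is.array(mean_intensity_db), length(dim(mean_intensity_db)) == 3L)
  if (any(!is.finite(mean_intensity_db))) {
    stop_doct("mean intensity volume contains non-finite values")
  }
  thr <- if (identical(cfg$intensity_threshold_db, "otsu")) {
    otsu_threshold_db(mean_intensity_db)
  } else {
    as.numeric(cfg$intensity_threshold_db)
  }
  bin <- mean_intensity_db > thr
  if (!any(bin)) {
    stop_doct("no spheroid found (threshold %.2f dB is above every voxel)", thr)
  }
  plate_depth <- NA_integer_
  D <- dim(bin)[2]
  plate_rows <- integer(0)
  if (!is.null(plate_mask)) {
    bin[as.logical(plate_mask)] <- FALSE
  } else if (cfg$plate_removal == "auto") {
    plate_depth <- detect_plate_depth(bin, mean_intensity_db)
    if (!is.na(plate_depth)) {
      plate_rows <- max(1L, plate_depth - 2L):min(D, plate_depth + 2L)
      bin[, plate_rows, ] <- FALSE
    }
  }
  for (i in seq_len(dim(bin)[1])) {
    bin[i, , ] <- largest_region_2d(bin[i, , ])
  }
  bin <- largest_component_3d(bin)
  if (cfg$closing_radius > 0L) {
    brush <- EBImage::makeBrush(2L * cfg$closing_radius + 1L, shape = "disc")
    for (i in seq_len(dim(bin)[1])) {
      bin[i, , ] <- EBImage::closing(bin[i, , ], brush) > 0
    }
    if (length(plate_rows)) bin[, plate_rows, ] <- FALSE
    if (!is.null(plate_mask)) bin[as.logical(plate_mask)] <- FALSE
  }
  if (sum(bin) < cfg$min_component_voxels) {
    stop_doct("no spheroid found (threshold %.2f dB: largest component has %d < %d voxels)",
              thr, sum(bin), cfg$min_component_voxels)
  }
  structure(
    list(mask = bin,
         voxel_volume_mm3 = if (!is.null(protocol)) voxel_volume_mm3(protocol) else NA_real_,
         threshold_db = thr, plate_depth = plate_depth, config = cfg),
    class = "segmentation_mask"
  )
}

is_segmentation_mask <- function(x) inherits(x, "segmentation_mask")

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d voxels (%.4g mm^3), threshold %.2f dB, plate depth %s\n",
              sum(x$mask), sum(x$mask) * x$voxel_volume_mm3, x$threshold_db,
              ifelse(is.na(x$plate_depth), "none", x$plate_depth)))
  invisible(x)
}
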