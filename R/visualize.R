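#' Pseudo-color mapping specification
#'
#' The composite follows the standard D-OCT rendering: hue encodes the
#' dynamics metric, value (brightness) encodes the mean OCT intensity, and
#' saturation is 1 everywhere. Out-of-range values clamp to the endpoints.
#'
#' @param metric_range `(low, high)` in metric units mapped onto the hue ramp.
#' @param intensity_range_db `(low, high)` dB mapped onto value in \[0, 1\].
#' @param hue_endpoints `(hue_low, hue_high)` in degrees; default 0 (red) to
#'   120 (green), so low dynamics renders red and high dynamics green.
#' @return A `colormap_spec` object.
#' @export
colormap_spec <- function(metric_range, intensity_range_db,
                          hue_endpoints = c(0, 120)) {
  stopifnot(length(metric_range) == 2L, length(intensity_range_db) == 2L,
            length(hue_endpoints) == 2L)
  if (metric_range[2] <= metric_range[1]) {
    stop_doct("metric_range must satisfy low < high")
  }
  if (intensity_range_db[2] <= intensity_range_db[1]) {
    stop_doct("intensity_range_db must satisfy low < high")
  }
  structure(
    list(metric_range = as.numeric(metric_range),
         intensity_range_db = as.numeric(intensity_range_db),
         hue_endpoints = as.numeric(hue_endpoints)),
    class = "colormap_spec"
  )
}

is_colormap_spec <- function(x) inherits(x, "colormap_spec")

#' Default display ranges per metric
#'
#' LIV 0..10 dB^2, OCDS_l 0..5e-4 1/ms (the dead-cell cut-offs of 3 dB^2 and
#' 2e-4 1/ms sit in the lower half of each ramp); intensity -25..5 dB.
#'
#' @param metric `"LIV"` or `"OCDS_l"`.
#' @param intensity_range_db Value-channel range in dB.
#' @return A [colormap_spec()].
#' @export
default_colormap <- function(metric = c("LIV", "OCDS_l"),
                             intensity_range_db = c(-25, 5)) {
  metric <- match.arg(metric)
  rng <- if (metric == "LIV") c(0, 10) else c(0, 5e-4)
  colormap_spec(rng, intensity_range_db)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Compose a hue/value pseudo-color volume
#'
#' Per voxel, HSV = (linear map of the metric into the hue ramp, 1, linear
#' map of the mean dB intensity into \[0, 1\]), converted to RGB. The
#' composition is per-voxel, so it commutes with slicing.
#'
#' @param metric A `dynamics_volume`.
#' @param spec A [colormap_spec()]; default from [default_colormap()].
#' @return A 4D array `[location, depth, lateral, 3]` of RGB in \[0, 1\].
#' @export
compose_pseudocolor <- function(metric, spec = NULL) {
  stopifnot(is_dynamics_volume(metric))
  spec <- spec %||% default_colormap(metric$metric)
  stopifnot(is_colormap_spec(spec))
  mr <- spec$metric_range; ir <- spec$intensity_range_db
  tm <- clamp01((as.vector(metric$values) - mr[1]) / (mr[2] - mr[1]))
  tv <- clamp01((as.vector(metric$mean_intensity_db) - ir[1]) / (ir[2] - ir[1]))
  hue_deg <- spec$hue_endpoints[1] + tm * diff(spec$hue_endpoints)
  cols <- grDevices::hsv(h = (hue_deg %% 360) / 360, s = 1, v = tv)
  rgb <- t(grDevices::col2rgb(cols)) / 255
  array(rgb, dim = c(dim(metric$values), 3L))
}

slice_array <- function(volume, axis, index) {
  if (is_dynamics_volume(volume)) volume <- volume$values
  d <- dim(volume)
  nd <- length(d)
  stopifnot(nd %in% c(3L, 4L))
  if (index < 1L || index > d[axis]) {
    stop_doct("slice index %d out of bounds [1, %d]", index, d[axis])
  }
  out <- if (axis == 2L) {
    if (nd == 3L) volume[, index, ] else volume[, index, , , drop = TRUE]
  } else {
    if (nd == 3L) volume[index, , ] else volume[index, , , , drop = TRUE]
  }
  attr(out, "plane") <- if (axis == 2L) "enface" else "bscan"
  attr(out, "index") <- as.integer(index)
  out
}

#' Extract an en face or cross-sectional slice
#'
#' `extract_en_face()` takes the plane at a fixed depth (location x lateral);
#' `extract_cross_section()` takes the B-scan at one location
#' (depth x lateral). Both work on 3D metric/intensity volumes, on
#' `dynamics_volume` objects, and on 4D RGB composites; the returned slice
#' carries `plane` and `index` attributes.
#'
#' @param volume 3D array, `dynamics_volume`, or 4D RGB array.
#' @param depth_index,location_index 1-based slice index.
#' @return A 2D matrix (or `rows x cols x 3` array for RGB input).
#' @export
extract_en_face <- function(volume, depth_index) {
  slice_array(volume, 2L, depth_index)
}

#' @rdname extract_en_face
#' @export
extract_cross_section <- function(volume, location_index) {
  slice_array(volume, 1L, location_index)
}

#' Centre planes of a segmented spheroid
#'
#' The "centre" slice is the one maximising in-mask area, found by exhaustive
#' counting (ties break to the first index).
#'
#' @param mask A [segment_spheroid()] result or a logical 3D array.
#' @return 1-based index of the depth (`center_depth`) or location
#'   (`center_location`) plane with the largest in-mask area.
#' @export
center_depth <- function(mask) {
  m <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  which.max(apply(m, 2, sum))
}

#' @rdname center_depth
#' @export
center_location <- function(mask) {
  m <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  which.max(apply(m, 1, sum))
}

#' Write a slice to PNG with a JSON sidecar of the display mapping
#'
#' @param slice 2D grayscale matrix (values clamped to \[0, 1\]) or
#'   `rows x cols x 3` RGB array.
#' @param path Output PNG path.
#' @param metadata Optional list written to `<path>.json` (e.g. colorbar
#'   limits, plane, index).
#' @return `path`, invisibly.
#' @export
render_slice_png <- function(slice, path, metadata = NULL) {
  img <- array(clamp01(as.numeric(slice)), dim = dim(slice))
  png::writePNG(img, target = path)
  if (!is.null(metadata)) {
    jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
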