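#' Define a repeated-B-scan volumetric acquisition protocol
#'
#' A D-OCT volume is acquired as a block-repeat raster: the lateral field of
#' view is split into `n_blocks` blocks of `locations_per_block` B-scan
#' locations each; within a block the raster over its locations is repeated
#' `n_repeats` times, so each B-scan location yields a time sequence of
#' `n_repeats` frames spaced `frame_interval` milliseconds apart. The defaults
#' are the standard protocol: 8 blocks x 16 locations x 32 repeats at
#' 204.8 ms over a 1 x 1 mm field of view, i.e. 128 B-scan locations and 4096
#' frames per volume, with a per-location time span of 6348.8 ms.
#'
#' @param n_blocks Number of raster blocks.
#' @param locations_per_block B-scan locations per block.
#' @param n_repeats Repeated frames per B-scan location.
#' @param frame_interval Inter-frame time at one location, in milliseconds.
#' @param fov_lateral Lateral field of view, mm, length-2 `(fast, slow)` where
#'   the fast axis is within a B-scan and the slow axis steps across B-scan
#'   locations.
#' @param a_lines_per_frame Lateral pixels (A-lines) per B-scan.
#' @param n_depth_pixels Depth pixels per A-line.
#' @param depth_pixel_size Depth pixel pitch, micrometres.
#' @return A `scan_protocol` object (list) with the derived fields
#'   `n_locations`, `lateral_pixel_size` (um) and `location_spacing` (um).
#' @examples
#' p <- scan_protocol()
#' p$n_locations # 128
#' @export
scan_protocol <- function(n_blocks = 8,
                          locations_per_block = 16,
                          n_repeats = 32,
                          frame_interval = 204.8,
                          fov_lateral = c(1, 1),
                          a_lines_per_frame = 128,
                          n_depth_pixels = 256,
                          depth_pixel_size = 7.8125) {
  n_blocks <- assert_count(n_blocks, "n_blocks")
  locations_per_block <- assert_count(locations_per_block, "locations_per_block")
  n_repeats <- assert_count(n_repeats, "n_repeats")
  frame_interval <- assert_positive(frame_interval, "frame_interval")
  if (length(fov_lateral) == 1L) fov_lateral <- rep(fov_lateral, 2L)
  stopifnot(length(fov_lateral) == 2L, all(fov_lateral > 0))
  a_lines_per_frame <- assert_count(a_lines_per_frame, "a_lines_per_frame")
  n_depth_pixels <- assert_count(n_depth_pixels, "n_depth_pixels")
  depth_pixel_size <- assert_positive(depth_pixel_size, "depth_pixel_size")
  n_locations <- n_blocks * locations_per_block
  structure(
    list(
      n_blocks = n_blocks,
      locations_per_block = locations_per_block,
      n_locations = n_locations,
      n_repeats = n_repeats,
      frame_interval = frame_interval,
      fov_lateral = as.numeric(fov_lateral),
      a_lines_per_frame = a_lines_per_frame,
      n_depth_pixels = n_depth_pixels,
      depth_pixel_size = depth_pixel_size,
      lateral_pixel_size = fov_lateral[1] * 1000 / a_lines_per_frame,
      location_spacing = fov_lateral[2] * 1000 / n_locations
    ),
    class = "scan_protocol"
  )
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf(
    paste0("<scan_protocol> %d blocks x %d locations x %d repeats @ %.1f ms\n",
           "  grid: %d locations x %d depth x %d lateral px; FOV %.2f x %.2f mm\n",
           "  voxel: %.3f (slow) x %.3f (depth) x %.3f (lateral) um\n"),
    x$n_blocks, x$locations_per_block, x$n_repeats, x$frame_interval,
    x$n_locations, x$n_depth_pixels, x$a_lines_per_frame,
    x$fov_lateral[1], x$fov_lateral[2],
    x$location_spacing, x$depth_pixel_size, x$lateral_pixel_size))
  invisible(x)
}

is_scan_protocol <- function(x) inherits(x, "scan_protocol")

#' Reduced-scale protocol used for phantom studies
#'
#' Same timing as [scan_protocol()] (32 repeats at 204.8 ms) on a smaller
#' spatial grid (24 B-scan locations x 48 depth x 48 lateral pixels over a
#' 0.75 x 0.75 mm field of view), sized so that a full 90-spheroid synthetic
#' study runs on a desktop in minutes. The dynamics contrasts only depend on
#' the per-location temporal sampling, which is unchanged.
#'
#' @param ... Overrides passed to [scan_protocol()].
#' @return A `scan_protocol`.
#' @export
study_protocol <- function(...) {
  args <- list(
    n_blocks = 4, locations_per_block = 6, n_repeats = 32,
    frame_interval = 204.8, fov_lateral = c(0.75, 0.75),
    a_lines_per_frame = 48, n_depth_pixels = 48, depth_pixel_size = 15.625
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scan_protocol, args)
}

#' Acquisition schedule of a block-repeat raster protocol
#'
#' Expands a protocol into its ordered frame schedule: blocks are scanned in
#' sequence; within a block one full raster pass over its locations
#' constitutes one repeat, and the pass is repeated `n_repeats` times. All
#' frames of one pass share the pass's nominal timestamp, so per-location
#' timestamps are uniformly spaced at `frame_interval`. Inter-block flyback
#' is not modelled: block `b` starts at
#' `(b - 1) * n_repeats * frame_interval`.
#'
#' @param protocol A [scan_protocol()].
#' @return A tibble with one row per frame, columns `block`, `location`
#'   (global, 1-based), `repeat_index` and `time_ms`, in acquisition order.
#' @examples
#' sched <- frame_schedule(scan_protocol())
#' nrow(sched) # 4096
#' @export
frame_schedule <- function(protocol) {
  stopifnot(is_scan_protocol(protocol))
  p <- protocol
  block_span <- p$n_repeats * p$frame_interval
  grid <- tidyr::expand_grid(
    block = seq_len(p$n_blocks),
    repeat_index = seq_len(p$n_repeats),
    within = seq_len(p$locations_per_block)
  )
  tibble(
    block = grid$block,
    location = (grid$block - 1L) * p$locations_per_block + grid$within,
    repeat_index = grid$repeat_index,
    time_ms = (grid$block - 1) * block_span + (grid$repeat_index - 1) * p$frame_interval
  )
}

#' Per-location repeat timestamps
#'
#' @param protocol A [scan_protocol()].
#' @return Numeric vector `0, frame_interval, ...` of length `n_repeats` (ms).
#' @export
repeat_times <- function(protocol) {
  stopifnot(is_scan_protocol(protocol))
  (seq_len(protocol$n_repeats) - 1) * protocol$frame_interval
}

#' Voxel volume implied by a protocol
#'
#' @param protocol A [scan_protocol()].
#' @return Voxel volume in mm^3 (slow-axis pitch x depth pitch x lateral pitch).
#' @export
voxel_volume_mm3 <- function(protocol) {
  stopifnot(is_scan_protocol(protocol))
  protocol$location_spacing * protocol$depth_pixel_size *
    protocol$lateral_pixel_size * 1e-9
}
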