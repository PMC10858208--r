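#' Construct a repeated-frame OCT time series
#'
#' The raw input of every dynamics contrast: for each B-scan location, a
#' stack of repeated linear-intensity frames with uniform timestamps.
#'
#' @param intensity 4D non-negative array indexed
#'   `[location, repeat, depth, lateral]`, linear intensity scale.
#' @param protocol The [scan_protocol()] the array must be consistent with.
#' @param provenance Free-text metadata (phantom seed, acquisition id, ...).
#' @return A `frame_timeseries` object: list with `intensity`, `timestamps`
#'   (ms, from [repeat_times()]), `protocol`, `provenance`.
#' @export
frame_timeseries <- function(intensity, protocol, provenance = "") {
  stopifnot(is_scan_protocol(protocol))
  if (!is.array(intensity) || length(dim(intensity)) != 4L) {
    stop_doct("`intensity` must be a 4D array [location, repeat, depth, lateral]")
  }
  expected <- c(protocol$n_locations, protocol$n_repeats,
                protocol$n_depth_pixels, protocol$a_lines_per_frame)
  if (!identical(as.integer(dim(intensity)), as.integer(expected))) {
    stop_doct("intensity dims [%s] do not match protocol [%s]",
              paste(dim(intensity), collapse = ","),
              paste(expected, collapse = ","))
  }
  if (anyNA(intensity) || min(intensity) < 0) {
    stop_doct("intensity must be non-negative and free of NA")
  }
  structure(
    list(
      intensity = intensity,
      timestamps = repeat_times(protocol),
      protocol = protocol,
      provenance = as.character(provenance)
    ),
    class = "frame_timeseries"
  )
}

is_frame_timeseries <- function(x) inherits(x, "frame_timeseries")

#' @export
print.frame_timeseries <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<frame_timeseries> %d locations x %d repeats x %d depth x %d lateral\n  span %.1f ms @ %.1f ms; provenance: %s\n",
    d[1], d[2], d[3], d[4], max(x$timestamps), x$protocol$frame_interval,
    if (nzchar(x$provenance)) x$provenance else "<none>"))
  invisible(x)
}

protocol_to_list <- function(p) {
  list(
    n_blocks = p$n_blocks,
    locations_per_block = p$locations_per_block,
    n_repeats = p$n_repeats,
    frame_interval = p$frame_interval,
    fov_lateral = p$fov_lateral,
    a_lines_per_frame = p$a_lines_per_frame,
    n_depth_pixels = p$n_depth_pixels,
    depth_pixel_size = p$depth_pixel_size
  )
}

protocol_from_list <- function(l) {
  scan_protocol(
    n_blocks = l$n_blocks,
    locations_per_block = l$locations_per_block,
    n_repeats = l$n_repeats,
    frame_interval = l$frame_interval,
    fov_lateral = unlist(l$fov_lateral),
    a_lines_per_frame = l$a_lines_per_frame,
    n_depth_pixels = l$n_depth_pixels,
    depth_pixel_size = l$depth_pixel_size
  )
}

loc_filename <- function(i) sprintf("loc_%03d.tif", i - 1L)

#' Write / read an OCT time series as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit float multi-page TIFF per B-scan location
#' (`loc_000.tif`, ...; pages = repeats, each page depth x lateral) and a
#' `protocol.json` sidecar holding the protocol (snake_case keys; times in
#' ms, lengths in um, FOV in mm), the provenance string and the global
#' `intensity_scale` by which frames were divided before storage (TIFF float
#' samples are kept in \[0, 1\]). The round trip is lossless to 32-bit float
#' precision.
#'
#' @param series A [frame_timeseries()].
#' @param path Directory to create/fill.
#' @return `write_timeseries()` returns `path` invisibly; `read_timeseries()`
#'   returns a [frame_timeseries()].
#' @export
write_timeseries <- function(series, path) {
  stopifnot(is_frame_timeseries(series))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  scale <- max(series$intensity)
  if (scale <= 0) scale <- 1
  p <- series$protocol
  for (i in seq_len(p$n_locations)) {
    pages <- lapply(seq_len(p$n_repeats), function(r) {
      series$intensity[i, r, , ] / scale
    })
    tiff::writeTIFF(pages, file.path(path, loc_filename(i)),
                    bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
  }
  sidecar <- c(protocol_to_list(p),
               list(provenance = series$provenance, intensity_scale = scale))
  jsonlite::write_json(sidecar, file.path(path, "protocol.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  sidecar_path <- file.path(path, "protocol.json")
  if (!file.exists(sidecar_path)) {
    stop_doct("missing sidecar %s", sidecar_path)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  p <- protocol_from_list(sc)
  scale <- sc$intensity_scale %||% 1
  intensity <- array(0, dim = c(p$n_locations, p$n_repeats,
                                p$n_depth_pixels, p$a_lines_per_frame))
  for (i in seq_len(p$n_locations)) {
    f <- file.path(path, loc_filename(i))
    if (!file.exists(f)) {
      stop_doct("location %d: missing frame file %s", i - 1L, f)
    }
    pages <- tiff::readTIFF(f, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != p$n_repeats) {
      stop_doct("location %d: sidecar declares %d repeats but TIFF has %d pages",
                i - 1L, p$n_repeats, length(pages))
    }
    for (r in seq_len(p$n_repeats)) {
      page <- pages[[r]]
      if (!identical(dim(page)[1:2],
                     c(p$n_depth_pixels, p$a_lines_per_frame))) {
        stop_doct("location %d: page %d is %s, expected %d x %d", i - 1L, r,
                  paste(dim(page), collapse = " x "),
                  p$n_depth_pixels, p$a_lines_per_frame)
      }
      intensity[i, r, , ] <- page * scale
    }
  }
  frame_timeseries(intensity, p, provenance = sc$provenance %||% "")
}
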