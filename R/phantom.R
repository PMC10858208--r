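#' Temporal-speckle dynamics parameters of a tissue region
#'
#' The speckle field of a region is modelled as a static plus a dynamic
#' circular complex Gaussian component,
#' `E(t) = sqrt(1 - m) E_s + sqrt(m) E_d(t)`, where the dynamic component
#' decorrelates exponentially with time constant `tau_c`. `m` plays the role
#' of the magnitude of intracellular motility (fraction of field power that
#' fluctuates) and `1 / tau_c` the role of its speed.
#'
#' @param m Motility fraction in \[0, 1\].
#' @param tau_c Field decorrelation time, ms (> 0).
#' @param mean_reflectivity Mean linear backscatter intensity of the region.
#' @param dead_fraction Fraction of the region's voxels rendered fully static
#'   (`m = 0`) at simulation time, emulating scattered dead cells whose
#'   dynamics have collapsed. In \[0, 1\].
#' @return A `region_dynamics` object (list).
#' @export
region_dynamics <- function(m, tau_c, mean_reflectivity = 1,
                            dead_fraction = 0) {
  if (!is.numeric(m) || length(m) != 1L || m < 0 || m > 1) {
    stop_doct("`m` must be in [0, 1]")
  }
  tau_c <- assert_positive(tau_c, "tau_c")
  mean_reflectivity <- assert_positive(mean_reflectivity, "mean_reflectivity")
  if (dead_fraction < 0 || dead_fraction > 1) {
    stop_doct("`dead_fraction` must be in [0, 1]")
  }
  structure(list(m = as.numeric(m), tau_c = tau_c,
                 mean_reflectivity = mean_reflectivity,
                 dead_fraction = as.numeric(dead_fraction)),
            class = "region_dynamics")
}

is_region_dynamics <- function(x) inherits(x, "region_dynamics")

#' Specify a synthetic spheroid phantom
#'
#' Geometry of an ellipsoidal spheroid (viable shell with an optional
#' concentric necrotic core and a smoothly perturbed boundary) resting above
#' a bright plate-bottom reflection plane, plus per-region speckle dynamics.
#' Axis order throughout is `[location (slow), depth, lateral]`; depth
#' increases away from the lens, and the plate lies below the spheroid.
#'
#' @param protocol [scan_protocol()] defining the voxel grid and pitches.
#' @param radii_um Ellipsoid radii in micrometres, `(slow, depth, lateral)`.
#' @param center_vox Spheroid centre in (possibly fractional) voxel indices,
#'   `(location, depth, lateral)`. Default: lateral/slow grid centre, depth
#'   such that the spheroid bottom sits 2 voxels above the plate.
#' @param boundary_perturbation Relative amplitude in \[0, 1\] of a smooth
#'   angular perturbation of the boundary radius (shape corruption).
#' @param core_fraction Necrotic-core radius relative to the spheroid radius,
#'   in \[0, 1).
#' @param shell,core [region_dynamics()] of the viable shell and necrotic
#'   core. The core default is quasi-static: with a 6.35 s observation
#'   window, tissue reads as "dead" on both dynamics contrasts only when its
#'   fluctuation amplitude collapses below the noise floor.
#' @param region_overrides List of labelled sub-regions stamped (in order)
#'   into the spheroid tissue. Each element is a list with `name`,
#'   `dynamics` ([region_dynamics()]), and either
#'   `type = "sphere"` with `center_frac` (offset from the spheroid centre in
#'   units of the radii) and `radius_um`, or `type = "shell"` with
#'   `r_lo_frac`, `r_hi_frac` (radial band in units of the spheroid radius).
#' @param plate_depth Depth index of the plate plane (default
#'   `round(0.88 * n_depth_pixels)`).
#' @param plate_reflectivity Linear reflectivity of the (static) plate plane.
#' @param noise_floor Mean of the additive exponential-intensity background.
#' @param psf_lateral_fwhm,psf_axial_fwhm Gaussian PSF full widths at half
#'   maximum, micrometres (defaults 18.1 and 14).
#' @param dead_patch_sigma_vox Gaussian correlation length (voxels, per axis
#'   `(location, depth, lateral)`) of the dead-cell field: regions with a
#'   nonzero `dead_fraction` lose contiguous patches of this scale rather
#'   than isolated voxels, emulating focal cell death. With the finite PSF an
#'   isolated static voxel still inherits its neighbours' fluctuations, so
#'   only patch interiors read as fully static - as in real images, where
#'   dead tissue appears in resolvable domains.
#' @param seed Integer seed for the boundary perturbation and voxel-level
#'   dead-cell draws.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(protocol,
                         radii_um,
                         center_vox = NULL,
                         boundary_perturbation = 0,
                         core_fraction = 0,
                         shell = region_dynamics(0.8, 600, 1),
                         core = region_dynamics(0, 3000, 0.6),
                         region_overrides = list(),
                         plate_depth = NULL,
                         plate_reflectivity = 10,
                         noise_floor = 1e-3,
                         psf_lateral_fwhm = 18.1,
                         psf_axial_fwhm = 14,
                         dead_patch_sigma_vox = c(1.5, 3, 3),
                         seed = 1) {
  stopifnot(is_scan_protocol(protocol), length(radii_um) == 3L,
            all(radii_um > 0), is_region_dynamics(shell),
            is_region_dynamics(core))
  if (boundary_perturbation < 0 || boundary_perturbation > 1) {
    stop_doct("`boundary_perturbation` must be in [0, 1]")
  }
  if (core_fraction < 0 || core_fraction >= 1) {
    stop_doct("`core_fraction` must be in [0, 1)")
  }
  dims <- grid_dims(protocol)
  plate_depth <- plate_depth %||% round(0.88 * protocol$n_depth_pixels)
  plate_depth <- assert_count(plate_depth, "plate_depth")
  if (plate_depth > protocol$n_depth_pixels) {
    stop_doct("plate_depth %d outside the %d-pixel depth grid",
              plate_depth, protocol$n_depth_pixels)
  }
  pitch <- voxel_pitches(protocol)
  if (is.null(center_vox)) {
    rz_vox <- radii_um[2] / pitch[2]
    center_vox <- c((dims[1] + 1) / 2,
                    plate_depth - rz_vox - 2,
                    (dims[3] + 1) / 2)
  }
  stopifnot(length(center_vox) == 3L)
  # spheroid (with maximal perturbation) must fit inside the grid
  reach_vox <- radii_um * (1 + boundary_perturbation) / pitch
  if (any(center_vox - reach_vox < 0.5) || any(center_vox + reach_vox > dims + 0.5)) {
    stop_doct("spheroid (radii %s um, perturbation %.2f) does not fit inside the %s grid",
              paste(radii_um, collapse = "/"), boundary_perturbation,
              paste(dims, collapse = "x"))
  }
  for (ov in region_overrides) validate_override(ov)
  structure(
    list(protocol = protocol, radii_um = as.numeric(radii_um),
         center_vox = as.numeric(center_vox),
         boundary_perturbation = as.numeric(boundary_perturbation),
         core_fraction = as.numeric(core_fraction),
         shell = shell, core = core, region_overrides = region_overrides,
         plate_depth = plate_depth,
         plate_reflectivity = assert_positive(plate_reflectivity, "plate_reflectivity"),
         noise_floor = as.numeric(noise_floor),
         psf_lateral_fwhm = as.numeric(psf_lateral_fwhm),
         psf_axial_fwhm = as.numeric(psf_axial_fwhm),
         dead_patch_sigma_vox = as.numeric(dead_patch_sigma_vox),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

is_phantom_spec <- function(x) inherits(x, "phantom_spec")

grid_dims <- function(protocol) {
  c(protocol$n_locations, protocol$n_depth_pixels, protocol$a_lines_per_frame)
}

# voxel pitches in um, axis order [location, depth, lateral]
voxel_pitches <- function(protocol) {
  c(protocol$location_spacing, protocol$depth_pixel_size,
    protocol$lateral_pixel_size)
}

validate_override <- function(ov) {
  if (is.null(ov$name) || is.null(ov$dynamics) || !is_region_dynamics(ov$dynamics)) {
    stop_doct("each region override needs `name` and `dynamics` (region_dynamics)")
  }
  type <- ov$type %||% "sphere"
  if (type == "sphere") {
    if (is.null(ov$center_frac) || length(ov$center_frac) != 3L ||
        is.null(ov$radius_um) || ov$radius_um <= 0) {
      stop_doct("sphere override '%s' needs center_frac (length 3) and radius_um > 0", ov$name)
    }
    if (any(abs(ov$center_frac) > 1.5)) {
      stop_doct("sphere override '%s' lies outside the phantom grid", ov$name)
    }
  } else if (type == "shell") {
    if (is.null(ov$r_lo_frac) || is.null(ov$r_hi_frac) ||
        ov$r_lo_frac < 0 || ov$r_hi_frac <= ov$r_lo_frac || ov$r_hi_frac > 1.5) {
      stop_doct("shell override '%s' needs 0 <= r_lo_frac < r_hi_frac <= 1.5", ov$name)
    }
  } else {
    stop_doct("unknown override type '%s'", type)
  }
  invisible(TRUE)
}

# Smooth random function on the unit sphere, |s| <= 1. Sum of a few cosines
# of projections onto random directions; low order keeps it smooth.
boundary_noise_fn <- function(seed, n_terms = 6) {
  with_seed(seed, {
    v <- matrix(rnorm(3 * n_terms), nrow = 3)
    v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
    k <- sample(1:3, n_terms, replace = TRUE)
    phase <- stats::runif(n_terms, 0, 2 * pi)
    w <- stats::runif(n_terms, 0.5, 1)
  })
  wsum <- sum(w)
  function(ux, uy, uz) {
    s <- 0
    for (j in seq_len(n_terms)) {
      proj <- ux * v[1, j] + uy * v[2, j] + uz * v[3, j]
      s <- s + w[j] * cos(k[j] * pi * proj + phase[j])
    }
    s / wsum
  }
}

#' Rasterize a phantom into a region label volume
#'
#' Labels: 0 background, 1 viable shell, 2 necrotic core (when
#' `core_fraction > 0`), 3+ region overrides (stamped last, in list order,
#' inside spheroid tissue only), and a final distinct label for the plate
#' plane (stamped across the full lateral extent outside spheroid labels).
#' The boundary radius is modulated by a smooth angular perturbation of
#' relative amplitude `boundary_perturbation`; the core is a concentric
#' unperturbed ellipsoid scaled by `core_fraction`.
#'
#' @param spec A [phantom_spec()].
#' @return A `region_label_volume`: list with `labels` (3D integer array
#'   `[location, depth, lateral]`), `label_table` (tibble: `label`, `name`,
#'   `m`, `tau_c`, `mean_reflectivity`, `dead_fraction`), `plate_label` and
#'   the generating `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(is_phantom_spec(spec))
  p <- spec$protocol
  dims <- grid_dims(p)
  pitch <- voxel_pitches(p)
  # physical offsets from centre, um, per axis
  dx <- (seq_len(dims[1]) - spec$center_vox[1]) * pitch[1]
  dz <- (seq_len(dims[2]) - spec$center_vox[2]) * pitch[2]
  dy <- (seq_len(dims[3]) - spec$center_vox[3]) * pitch[3]
  ex <- array(rep(dx / spec$radii_um[1], times = dims[2] * dims[3]), dim = dims)
  ez <- array(rep(rep(dz / spec$radii_um[2], each = dims[1]), times = dims[3]), dim = dims)
  ey <- array(rep(dy / spec$radii_um[3], each = dims[1] * dims[2]), dim = dims)
  rho <- sqrt(ex^2 + ez^2 + ey^2)
  labels <- array(0L, dim = dims)
  if (spec$boundary_perturbation > 0) {
    sfun <- boundary_noise_fn(spec$seed)
    nz <- rho > 0
    s <- array(0, dim = dims)
    s[nz] <- sfun(ex[nz] / rho[nz], ey[nz] / rho[nz], ez[nz] / rho[nz])
    inside <- rho <= 1 + spec$boundary_perturbation * s
  } else {
    inside <- rho <= 1
  }
  labels[inside] <- 1L
  rows <- list(region_row(1L, "shell", spec$shell))
  next_label <- 3L  # label 2 is reserved for the core, present or not
  if (spec$core_fraction > 0) {
    labels[rho <= spec$core_fraction] <- 2L
    rows <- c(rows, list(region_row(2L, "core", spec$core)))
  }
  tissue <- labels > 0L
  for (ov in spec$region_overrides) {
    type <- ov$type %||% "sphere"
    if (type == "sphere") {
      c_um <- ov$center_frac * spec$radii_um
      d2 <- (ex * spec$radii_um[1] - c_um[1])^2 +
            (ez * spec$radii_um[2] - c_um[2])^2 +
            (ey * spec$radii_um[3] - c_um[3])^2
      sel <- tissue & (d2 <= ov$radius_um^2)
    } else {
      sel <- tissue & rho >= ov$r_lo_frac & rho <= ov$r_hi_frac
    }
    labels[sel] <- next_label
    rows <- c(rows, list(region_row(next_label, ov$name, ov$dynamics)))
    next_label <- next_label + 1L
  }
  plate_label <- next_label
  plate_slab <- labels[, spec$plate_depth, ] == 0L
  labels[, spec$plate_depth, ][plate_slab] <- plate_label
  rows <- c(rows, list(region_row(
    plate_label, "plate",
    region_dynamics(0, 1000, spec$plate_reflectivity))))
  structure(
    list(labels = labels, label_table = bind_rows(rows),
         plate_label = plate_label, spec = spec),
    class = "region_label_volume"
  )
}

#' Uniform single-region label volume for calibration and oracle checks
#'
#' Fills the whole grid with one region of the given dynamics - no geometry,
#' no plate. Useful for estimator calibration against the closed-form
#' correlation oracles, where a statistically homogeneous voxel population
#' is needed.
#'
#' @param protocol A [scan_protocol()].
#' @param dynamics A [region_dynamics()].
#' @param noise_floor Mean of the additive exponential background.
#' @param psf_lateral_fwhm,psf_axial_fwhm PSF FWHMs in um (default 0: no
#'   spatial filtering, so voxels stay statistically independent).
#' @param seed Seed stored in the embedded spec.
#' @return A `region_label_volume`.
#' @export
uniform_label_volume <- function(protocol, dynamics, noise_floor = 0,
                                 psf_lateral_fwhm = 0, psf_axial_fwhm = 0,
                                 seed = 1) {
  stopifnot(is_scan_protocol(protocol), is_region_dynamics(dynamics))
  dims <- grid_dims(protocol)
  spec <- structure(
    list(protocol = protocol, noise_floor = as.numeric(noise_floor),
         psf_lateral_fwhm = as.numeric(psf_lateral_fwhm),
         psf_axial_fwhm = as.numeric(psf_axial_fwhm),
         dead_patch_sigma_vox = c(1.5, 3, 3), seed = as.integer(seed)),
    class = "phantom_spec")
  structure(
    list(labels = array(1L, dim = dims),
         label_table = region_row(1L, "uniform", dynamics),
         plate_label = NA_integer_, spec = spec),
    class = "region_label_volume")
}

region_row <- function(label, name, dyn) {
  tibble(label = as.integer(label), name = name, m = dyn$m, tau_c = dyn$tau_c,
         mean_reflectivity = dyn$mean_reflectivity,
         dead_fraction = dyn$dead_fraction)
}

is_region_label_volume <- function(x) inherits(x, "region_label_volume")

#' @export
print.region_label_volume <- function(x, ...) {
  cat(sprintf("<region_label_volume> %s grid, %d regions\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$label_table)))
  print(x$label_table)
  invisible(x)
}
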