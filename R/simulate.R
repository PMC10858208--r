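complex_normal <- function(n) {
  complex(real = rnorm(n), imaginary = rnorm(n)) / sqrt(2)
}

# 2D wrapped Gaussian kernel in the frequency domain, L2-normalised in the
# space domain so that filtering preserves the variance of white noise.
psf_kernel_fft <- function(n_depth, n_lateral, sigma_depth_px, sigma_lateral_px) {
  if (sigma_depth_px <= 0 && sigma_lateral_px <= 0) return(NULL)
  wrap_gauss <- function(n, sigma) {
    if (sigma <= 0) return(c(1, rep(0, n - 1)))
    d <- 0:(n - 1)
    d <- pmin(d, n - d)
    exp(-d^2 / (2 * sigma^2))
  }
  k <- outer(wrap_gauss(n_depth, sigma_depth_px),
             wrap_gauss(n_lateral, sigma_lateral_px))
  k <- k / sqrt(sum(k^2))
  stats::fft(k)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Smooth standard-normal-ish random field via FFT convolution with a wrapped
# 3D Gaussian (separable, L2-normalised). Used for patchy dead-cell draws.
smooth_random_field <- function(dims, sigma_vox) {
  wrap_gauss <- function(n, sigma) {
    if (sigma <= 0) return(c(1, rep(0, n - 1)))
    d <- 0:(n - 1)
    d <- pmin(d, n - d)
    exp(-d^2 / (2 * sigma^2))
  }
  k <- outer(outer(wrap_gauss(dims[1], sigma_vox[1]),
                   wrap_gauss(dims[2], sigma_vox[2])),
             wrap_gauss(dims[3], sigma_vox[3]))
  dim(k) <- dims
  k <- k / sqrt(sum(k^2))
  w <- array(rnorm(prod(dims)), dim = dims)
  Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) / prod(dims)
}

# Per-voxel logical "dead" field: within each region that has dead_fraction
# > 0, exactly that quantile of a spatially correlated Gaussian field is
# marked dead, so death arrives in contiguous patches of the requested scale.
draw_dead_voxels <- function(lab1, df_v, dims, sigma_vox) {
  dead <- rep(FALSE, length(lab1))
  if (!any(df_v > 0)) return(dead)
  field <- as.vector(smooth_random_field(dims, sigma_vox))
  for (lb in unique(lab1[df_v > 0])) {
    sel <- lab1 == lb
    f <- df_v[sel][1]
    thr <- stats::quantile(field[sel], probs = f, names = FALSE)
    dead[sel] <- field[sel] < thr
  }
  dead
}

#' Simulate an OCT speckle time series from a region label volume
#'
#' Per voxel the complex field is
#' `E(t) = sqrt(1 - m) E_s + sqrt(m) E_d(t)` with `E_s` a static circular
#' complex Gaussian draw and `E_d` a stationary circular complex Gaussian
#' Ornstein-Uhlenbeck process with field correlation `exp(-|dt| / tau_c)`
#' (exact discrete recursion `E_d(t + D) = a E_d(t) + sqrt(1 - a^2) w`,
#' `a = exp(-D / tau_c)`). Each frame's field is low-pass filtered with the
#' Gaussian PSF (FWHM converted to sigma; kernel L2-normalised so white-noise
#' variance is preserved), then intensity `|E|^2` is scaled by the region's
#' mean reflectivity and an independent exponential-intensity background of
#' mean `noise_floor` is added. Plate voxels are static; regions with a
#' nonzero `dead_fraction` have that fraction of voxels forced static
#' (seeded Bernoulli draw). Output intensity is linear scale.
#'
#' @param regions A [build_phantom()] result.
#' @param protocol Optional [scan_protocol()]; defaults to the one in the
#'   phantom spec (the grids must agree).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param noise_floor,psf_lateral_fwhm,psf_axial_fwhm Overrides of the
#'   phantom-spec values.
#' @return A [frame_timeseries()].
#' @export
simulate_timeseries <- function(regions, protocol = NULL, seed = 1,
                                noise_floor = NULL,
                                psf_lateral_fwhm = NULL,
                                psf_axial_fwhm = NULL) {
  stopifnot(is_region_label_volume(regions))
  spec <- regions$spec
  protocol <- protocol %||% spec$protocol
  stopifnot(is_scan_protocol(protocol))
  dims <- dim(regions$labels)
  if (!identical(as.integer(dims), as.integer(grid_dims(protocol)))) {
    stop_doct("label volume %s does not match protocol grid %s",
              paste(dims, collapse = "x"),
              paste(grid_dims(protocol), collapse = "x"))
  }
  noise_floor <- noise_floor %||% spec$noise_floor
  psf_lateral_fwhm <- psf_lateral_fwhm %||% spec$psf_lateral_fwhm
  psf_axial_fwhm <- psf_axial_fwhm %||% spec$psf_axial_fwhm

  tab <- regions$label_table
  max_label <- max(tab$label)
  m_of <- refl_of <- tau_of <- df_of <- rep(0, max_label + 1L)
  tau_of[] <- 1
  m_of[tab$label + 1L] <- tab$m
  tau_of[tab$label + 1L] <- tab$tau_c
  refl_of[tab$label + 1L] <- tab$mean_reflectivity
  df_of[tab$label + 1L] <- tab$dead_fraction
  lab1 <- as.integer(regions$labels) + 1L
  n_vox <- length(lab1)
  m_v <- m_of[lab1]
  tau_v <- tau_of[lab1]
  refl_v <- refl_of[lab1]
  df_v <- df_of[lab1]
  refl_v[lab1 == 1L] <- 0  # background carries no field, only noise floor

  L <- dims[1]; D <- dims[2]; W <- dims[3]
  R <- protocol$n_repeats
  dt <- protocol$frame_interval
  kf <- psf_kernel_fft(D, W,
                       fwhm_to_sigma(psf_axial_fwhm) / protocol$depth_pixel_size,
                       fwhm_to_sigma(psf_lateral_fwhm) / protocol$lateral_pixel_size)
  intensity <- array(0, dim = c(L, R, D, W))
  with_seed(seed, {
    if (any(df_v > 0)) {
      dead <- draw_dead_voxels(lab1, df_v, dims,
                               spec$dead_patch_sigma_vox %||% c(1.5, 3, 3))
      m_v[dead] <- 0
    }
    a_v <- exp(-dt / tau_v)
    innov <- sqrt(pmax(0, 1 - a_v^2))
    ws <- sqrt(1 - m_v)
    wd <- sqrt(m_v)
    Es <- complex_normal(n_vox)
    Ed <- complex_normal(n_vox)
    for (t in seq_len(R)) {
      E <- ws * Es + wd * Ed
      if (!is.null(kf)) {
        Ea <- array(E, dim = dims)
        for (i in seq_len(L)) {
          Ea[i, , ] <- stats::fft(stats::fft(Ea[i, , ]) * kf,
                                  inverse = TRUE) / (D * W)
        }
        E <- as.vector(Ea)
      }
      I_t <- refl_v * Mod(E)^2
      if (noise_floor > 0) I_t <- I_t + rexp(n_vox, rate = 1 / noise_floor)
      intensity[, t, , ] <- I_t
      if (t < R) Ed <- a_v * Ed + innov * complex_normal(n_vox)
    }
  })
  frame_timeseries(intensity, protocol,
                   provenance = sprintf("phantom seed=%d", as.integer(seed)))
}

dilog <- function(x) {
  # Li2 on [0, 1]; series is slow near 1, so use the Euler reflection
  # Li2(x) + Li2(1-x) = pi^2/6 - log(x) log(1-x) for x > 1/2.
  vapply(x, function(xi) {
    if (xi <= 0) return(0)
    if (xi >= 1) return(pi^2 / 6)
    refl <- xi > 0.5
    z <- if (refl) 1 - xi else xi
    k <- seq_len(200)
    s <- sum(z^k / k^2)
    if (refl) pi^2 / 6 - log(xi) * log(1 - xi) - s else s
  }, numeric(1))
}

#' Closed-form intensity autocorrelation of the speckle model
#'
#' For the static-plus-dynamic circular Gaussian field model the normalized
#' field correlation is `g1(tau) = (1 - m) + m exp(-tau / tau_c)` and, by the
#' Siegert relation, the Pearson correlation of the intensity is
#' `rho(tau) = |g1(tau)|^2`. With `domain = "log_intensity"` (only defined
#' for fully developed speckle, `m = 1`) the correlation of the log-scaled
#' intensity is returned instead: `corr(ln I_1, ln I_2) = Li2(rho) / (pi^2/6)`
#' where `Li2` is the dilogarithm - the exact size of the dB-vs-linear
#' estimator bias.
#'
#' @param m Motility fraction in \[0, 1\].
#' @param tau_c Field decorrelation time, ms.
#' @param delays Non-negative delay times, ms.
#' @param domain `"intensity"` (Siegert, default) or `"log_intensity"`.
#' @return A `correlation_curve` tibble with columns `delay_ms`, `rho`;
#'   `rho` equals 1 at delay 0.
#' @examples
#' analytic_intensity_correlation(1, 409.6, c(0, 204.8, 409.6))
#' @export
analytic_intensity_correlation <- function(m, tau_c, delays,
                                           domain = c("intensity", "log_intensity")) {
  domain <- match.arg(domain)
  if (m < 0 || m > 1) stop_doct("`m` must be in [0, 1]")
  tau_c <- assert_positive(tau_c, "tau_c")
  if (any(delays < 0)) stop_doct("delays must be non-negative")
  g1 <- (1 - m) + m * exp(-delays / tau_c)
  rho <- g1^2
  if (domain == "log_intensity") {
    if (m != 1) {
      stop_doct("log-intensity correlation is only available in closed form for m = 1")
    }
    rho <- dilog(rho) / (pi^2 / 6)
  }
  structure(tibble(delay_ms = as.numeric(delays), rho = rho),
            class = c("correlation_curve", class(tibble())))
}

#' Voxel-pooled (ensemble) temporal autocorrelation
#'
#' Pools a statistically uniform set of voxels and estimates the lag
#' correlation using the ensemble grand mean and variance instead of
#' per-voxel temporal statistics. Unlike the per-voxel imaging estimator of
#' [compute_autocorrelation()], which with a short window is biased at long
#' decorrelation times (the per-voxel mean soaks up slow fluctuations), this
#' estimator is consistent as the number of pooled voxels grows, which makes
#' it the right empirical counterpart of
#' [analytic_intensity_correlation()].
#'
#' @param series A [frame_timeseries()].
#' @param voxels Optional logical array `[location, depth, lateral]`
#'   selecting the pooled voxels (default: all).
#' @param max_lag Largest lag, in frames.
#' @param domain `"linear"` (default; Siegert applies exactly) or `"db"`.
#' @return A `correlation_curve` tibble (`delay_ms`, `rho`), including the
#'   zero-delay row with `rho = 1`.
#' @export
pooled_autocorrelation <- function(series, voxels = NULL, max_lag = 6,
                                   domain = c("linear", "db")) {
  stopifnot(is_frame_timeseries(series))
  domain <- match.arg(domain)
  R <- series$protocol$n_repeats
  max_lag <- assert_count(max_lag, "max_lag")
  if (R < max_lag + 2L) stop_doct("need n_repeats >= max_lag + 2")
  X <- voxel_by_time(series$intensity)
  if (!is.null(voxels)) {
    X <- X[as.logical(as.vector(voxels)), , drop = FALSE]
  }
  if (domain == "db") X <- 10 * log10(X + 1e-6 * mean(X))
  Xc <- X - mean(X)
  den <- mean(Xc^2)
  if (den <= 0) stop_doct("pooled voxels have zero variance")
  rho <- vapply(seq_len(max_lag), function(k) {
    mean(Xc[, seq_len(R - k), drop = FALSE] *
           Xc[, (k + 1):R, drop = FALSE]) / den
  }, numeric(1))
  structure(
    tibble(delay_ms = c(0, seq_len(max_lag)) * series$protocol$frame_interval,
           rho = c(1, rho)),
    class = c("correlation_curve", class(tibble())))
}

# [location, repeat, depth, lateral] -> voxels x repeats matrix, voxel order
# matching as.vector() of a [location, depth, lateral] array.
voxel_by_time <- function(intensity) {
  d <- dim(intensity)
  matrix(aperm(intensity, c(1, 3, 4, 2)), ncol = d[2])
}
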