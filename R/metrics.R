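#' Configuration of the dynamics contrasts
#'
#' @param db_floor Small positive linear intensity added before the log.
#'   `NULL` (default) resolves at compute time to `1e-6` times the series
#'   mean intensity, which keeps zero-intensity voxels finite without biasing
#'   in-tissue voxels.
#' @param ocds_window Delay range, ms, over which the autocorrelation decay
#'   slope is fitted (default `c(204.8, 1228.8)`, the late window). The lower
#'   bound must be at least one frame interval and the window must contain at
#'   least two lags.
#' @param variance_divisor `"N"` (population variance over repeats, default)
#'   or `"N-1"`.
#' @param ocds_sign `"negated_slope"` (default; decay speed is positive so a
#'   faster decay gives a larger value, consistent with a positive dead-cell
#'   cut-off) or `"raw_slope"`.
#' @param correlation_domain `"db"` (default; the autocorrelation operates on
#'   the dB-scaled signal, like LIV) or `"linear"` (raw intensity, where the
#'   Siegert relation applies exactly - used for oracle comparisons).
#' @return A `metric_config` object.
#' @export
metric_config <- function(db_floor = NULL,
                          ocds_window = c(204.8, 1228.8),
                          variance_divisor = c("N", "N-1"),
                          ocds_sign = c("negated_slope", "raw_slope"),
                          correlation_domain = c("db", "linear")) {
  stopifnot(length(ocds_window) == 2L, all(ocds_window > 0))
  if (ocds_window[2] <= ocds_window[1]) {
    stop_doct("ocds_window upper bound must exceed the lower bound")
  }
  if (!is.null(db_floor)) db_floor <- assert_positive(db_floor, "db_floor")
  structure(
    list(db_floor = db_floor, ocds_window = as.numeric(ocds_window),
         variance_divisor = match.arg(variance_divisor),
         ocds_sign = match.arg(ocds_sign),
         correlation_domain = match.arg(correlation_domain)),
    class = "metric_config"
  )
}

is_metric_config <- function(x) inherits(x, "metric_config")

resolve_db_floor <- function(cfg, intensity) {
  cfg$db_floor %||% max(1e-6 * mean(intensity), .Machine$double.xmin)
}

#' dB scaling of linear OCT intensity
#'
#' `10 * log10(intensity + db_floor)`; the floor keeps zero intensity finite.
#'
#' @param intensity Non-negative linear-scale array or vector.
#' @param db_floor Small positive linear offset (default `1e-12`).
#' @return Same shape as the input, in dB.
#' @examples
#' to_db(c(1, 100)) # ~0 and ~20 dB
#' @export
to_db <- function(intensity, db_floor = 1e-12) {
  if (anyNA(intensity) || min(intensity) < 0) {
    stop_doct("intensity must be non-negative and free of NA")
  }
  db_floor <- assert_positive(db_floor, "db_floor")
  10 * log10(intensity + db_floor)
}

new_dynamics_volume <- function(values, metric, units, mean_intensity_db,
                                protocol) {
  stopifnot(identical(dim(values), dim(mean_intensity_db)))
  if (metric == "LIV" && min(values) < 0) {
    stop_doct("LIV values must be non-negative")
  }
  structure(
    list(values = values, metric = metric, units = units,
         mean_intensity_db = mean_intensity_db, protocol = protocol),
    class = "dynamics_volume"
  )
}

is_dynamics_volume <- function(x) inherits(x, "dynamics_volume")

#' @export
print.dynamics_volume <- function(x, ...) {
  cat(sprintf("<dynamics_volume> %s [%s], %s grid, range %.3g..%.3g\n",
              x$metric, x$units, paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Logarithmic intensity variance (LIV)
#'
#' Per voxel, the temporal variance of the dB-scaled OCT intensity over the
#' repeated frames - the magnitude contrast of intracellular motility. Units
#' dB^2. Also returns the temporal mean of the dB intensity, used as the
#' brightness channel of pseudo-color composites and for segmentation.
#'
#' @param series A [frame_timeseries()] with at least 2 repeats.
#' @param cfg A [metric_config()].
#' @return A `dynamics_volume` with `metric = "LIV"` and fields `values`
#'   (`[location, depth, lateral]`, dB^2) and `mean_intensity_db`.
#' @export
compute_liv <- function(series, cfg = metric_config()) {
  stopifnot(is_frame_timeseries(series), is_metric_config(cfg))
  R <- series$protocol$n_repeats
  if (R < 2L) stop_doct("LIV needs at least 2 repeated frames")
  floor_lin <- resolve_db_floor(cfg, series$intensity)
  X <- to_db(voxel_by_time(series$intensity), floor_lin)
  mu <- rowMeans(X)
  divisor <- if (cfg$variance_divisor == "N") R else R - 1L
  v <- rowSums((X - mu)^2) / divisor
  dims <- dim(series$intensity)[c(1, 3, 4)]
  new_dynamics_volume(array(v, dims), "LIV", "dB^2", array(mu, dims),
                      series$protocol)
}

# Integer lags whose delays fall inside the OCDS window. For the default
# window and 204.8 ms sampling this must be exactly lags 1..6.
window_lags <- function(cfg, frame_interval) {
  lo <- cfg$ocds_window[1]; hi <- cfg$ocds_window[2]
  if (lo < frame_interval - 1e-9) {
    stop_doct("ocds_window lower bound (%.1f ms) is below one frame interval (%.1f ms)",
              lo, frame_interval)
  }
  k_lo <- as.integer(ceiling(lo / frame_interval - 1e-9))
  k_hi <- as.integer(floor(hi / frame_interval + 1e-9))
  if (k_hi - k_lo + 1L < 2L) {
    stop_doct("ocds_window [%.1f, %.1f] ms contains fewer than 2 lags at %.1f ms sampling",
              lo, hi, frame_interval)
  }
  lags <- k_lo:k_hi
  if (isTRUE(all.equal(c(lo, hi), c(204.8, 1228.8))) &&
      isTRUE(all.equal(frame_interval, 204.8)) &&
      length(lags) != 6L) {
    stop_doct("internal error: default window must select exactly 6 lags")
  }
  lags
}

#' Per-voxel temporal autocorrelation of the OCT time sequence
#'
#' Sample Pearson autocorrelation of the (by default dB-scaled) sequence at
#' integer lags `k * frame_interval`: the series is centred with its full
#' temporal mean, normalised by the full-series variance (so `rho(0) = 1` by
#' construction), and the lag-`k` products are averaged over the `N - k`
#' available pairs. Voxels with (numerically) zero temporal variance are
#' flagged static and given the non-decaying `rho = 1` at all lags.
#'
#' @param series A [frame_timeseries()].
#' @param cfg A [metric_config()]; `correlation_domain` selects the dB or
#'   linear signal and `ocds_window` sets how many lags are needed.
#' @param max_lag Number of lags to compute (default: up to the last lag of
#'   the OCDS window).
#' @return An `autocorrelation_set`: list with `rho` (voxels x lags matrix),
#'   `delays` (ms), `static` (logical), `dims`, `mean_intensity_db`,
#'   `protocol`.
#' @export
compute_autocorrelation <- function(series, cfg = metric_config(),
                                    max_lag = NULL) {
  stopifnot(is_frame_timeseries(series), is_metric_config(cfg))
  R <- series$protocol$n_repeats
  dt <- series$protocol$frame_interval
  lags <- window_lags(cfg, dt)
  max_lag <- max_lag %||% max(lags)
  max_lag <- assert_count(max_lag, "max_lag")
  if (R < max_lag + 2L) {
    stop_doct("need n_repeats >= %d for %d lags (got %d)", max_lag + 2L,
              max_lag, R)
  }
  floor_lin <- resolve_db_floor(cfg, series$intensity)
  M <- voxel_by_time(series$intensity)
  mu_db <- rowMeans(to_db(M, floor_lin))
  X <- if (cfg$correlation_domain == "db") to_db(M, floor_lin) else M
  mu <- rowMeans(X)
  Xc <- X - mu
  den <- rowSums(Xc^2) / R
  ms <- rowMeans(X^2)
  static <- den <= 1e-10 * (ms + .Machine$double.xmin)
  den_safe <- ifelse(static, 1, den)
  rho <- matrix(0, nrow = nrow(X), ncol = max_lag)
  for (k in seq_len(max_lag)) {
    rho[, k] <- rowSums(Xc[, seq_len(R - k), drop = FALSE] *
                          Xc[, (k + 1):R, drop = FALSE]) / (R - k) / den_safe
  }
  rho[static, ] <- 1
  dims <- dim(series$intensity)[c(1, 3, 4)]
  structure(
    list(rho = rho, delays = seq_len(max_lag) * dt, static = static,
         dims = dims, mean_intensity_db = array(mu_db, dims),
         protocol = series$protocol, cfg = cfg),
    class = "autocorrelation_set"
  )
}

is_autocorrelation_set <- function(x) inherits(x, "autocorrelation_set")

ols_slope <- function(y_matrix, x) {
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  as.vector(y_matrix %*% xc) / sxx
}

#' Late OCT correlation decay speed (OCDS_l)
#'
#' Ordinary least-squares slope of the autocorrelation decay curve
#' `rho(tau)` over the lags whose delays fall in the late window (default
#' \[204.8, 1228.8\] ms, i.e. lags 1..6 at 204.8 ms sampling). With the
#' default sign convention the reported value is the negated slope, so that
#' faster decay means a larger, positive decay speed. Units 1/ms. Static
#' voxels (non-decaying `rho = 1`) get OCDS_l = 0; negative values at noisy
#' voxels are not clamped.
#'
#' @param curves An `autocorrelation_set` from [compute_autocorrelation()],
#'   or a single `correlation_curve` tibble (then a scalar is returned).
#' @param cfg A [metric_config()].
#' @return A `dynamics_volume` with `metric = "OCDS_l"` (units 1/ms), or a
#'   scalar for a single curve.
#' @export
compute_ocds <- function(curves, cfg = metric_config()) {
  stopifnot(is_metric_config(cfg))
  sign_factor <- if (cfg$ocds_sign == "negated_slope") -1 else 1
  if (inherits(curves, "correlation_curve") || is.data.frame(curves)) {
    sel <- curves$delay_ms >= cfg$ocds_window[1] - 1e-9 &
      curves$delay_ms <= cfg$ocds_window[2] + 1e-9
    if (sum(sel) < 2L) stop_doct("fewer than 2 in-window delays in the curve")
    return(sign_factor *
             ols_slope(matrix(curves$rho[sel], nrow = 1), curves$delay_ms[sel]))
  }
  stopifnot(is_autocorrelation_set(curves))
  dt <- curves$protocol$frame_interval
  lags <- window_lags(cfg, dt)
  if (max(lags) > ncol(curves$rho)) {
    stop_doct("autocorrelation set has %d lags but the window needs lag %d",
              ncol(curves$rho), max(lags))
  }
  slope <- ols_slope(curves$rho[, lags, drop = FALSE], lags * dt)
  values <- array(sign_factor * slope, curves$dims)
  new_dynamics_volume(values, "OCDS_l", "1/ms", curves$mean_intensity_db,
                      curves$protocol)
}

#' Both dynamics contrasts in one pass
#'
#' @param series A [frame_timeseries()].
#' @param cfg A [metric_config()].
#' @return List with elements `liv` and `ocds` (both `dynamics_volume`).
#' @export
compute_dynamics <- function(series, cfg = metric_config()) {
  list(liv = compute_liv(series, cfg),
       ocds = compute_ocds(compute_autocorrelation(series, cfg), cfg))
}
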