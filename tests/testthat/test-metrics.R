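test_that("dB conversion and its floor behave", {
  expect_equal(to_db(1), 0, tolerance = 1e-9)
  expect_equal(to_db(100), 20, tolerance = 1e-9)
  expect_equal(to_db(0, db_floor = 1e-12), 10 * log10(1e-12))
  expect_true(is.finite(to_db(0)))
  expect_error(to_db(-1), "non-negative")
})

# series whose every voxel holds the same temporal sequence
constant_pattern_series <- function(pattern, n_loc = 1, depth = 2, lateral = 2) {
  p <- tiny_protocol(n_loc = n_loc, n_repeats = length(pattern),
                     depth = depth, lateral = lateral)
  make_series(p, function(i, d, w) pattern)
}

test_that("LIV of deterministic sequences matches hand-computed variances", {
  cfg <- metric_config(db_floor = 1e-15)
  # constant sequence -> zero variance
  liv0 <- compute_liv(constant_pattern_series(rep(7.3, 32)), cfg)
  expect_equal(max(abs(liv0$values)), 0)
  # alternating 10 and 100 (10 dB and 20 dB): population variance 25 dB^2
  livA <- compute_liv(constant_pattern_series(rep(c(10, 100), 16)), cfg)
  expect_equal(as.vector(livA$values), rep(25, 4), tolerance = 1e-9)
  expect_equal(as.vector(livA$mean_intensity_db), rep(15, 4),
               tolerance = 1e-9)
  # sample-variance divisor rescales by N / (N - 1)
  livB <- compute_liv(constant_pattern_series(rep(c(10, 100), 16)),
                      metric_config(db_floor = 1e-15,
                                    variance_divisor = "N-1"))
  expect_equal(as.vector(livB$values), rep(25 * 32 / 31, 4),
               tolerance = 1e-9)
  expect_error(compute_liv(constant_pattern_series(5)), "at least 2")
})

test_that("LIV and lag correlations equal brute-force double loops (N = 8)", {
  p <- tiny_protocol(n_loc = 2, n_repeats = 8, depth = 3, lateral = 4)
  set.seed(31)
  series <- make_series(p, function(i, d, w) rlnorm(8, sdlog = 1.5))
  cfg <- metric_config(db_floor = 1e-15)
  liv <- compute_liv(series, cfg)
  ac <- compute_autocorrelation(series, cfg, max_lag = 3)
  X <- series$intensity
  vox <- 0L
  for (w in seq_len(4)) for (d in seq_len(3)) for (i in seq_len(2)) {
    # voxel order of the flattened [location, depth, lateral] array
    vox <- vox + 1L
    x <- X[i, , d, w]
    expect_equal(liv$values[i, d, w], brute_liv(x, 1e-15),
                 tolerance = 1e-12)
    for (k in 1:3) {
      expect_equal(ac$rho[vox, k],
                   brute_lag_correlation(10 * log10(x + 1e-15), k),
                   tolerance = 1e-12)
    }
  }
})

test_that("autocorrelation of forced patterns and static voxels", {
  cfg <- metric_config(db_floor = 1e-15)
  # deterministic alternation: rho(1 lag) = -1, rho(2 lags) = +1
  ac <- compute_autocorrelation(constant_pattern_series(rep(c(10, 100), 8)),
                                cfg, max_lag = 2)
  expect_equal(unique(ac$rho[, 1]), -1, tolerance = 1e-12)
  expect_equal(unique(ac$rho[, 2]), 1, tolerance = 1e-12)
  expect_false(any(ac$static))
  # constant-plus-tiny-jitter voxels are flagged and treated as non-decaying
  base <- rep(50, 16)
  jit <- base + c(1e-9, rep(0, 15))
  ac2 <- compute_autocorrelation(constant_pattern_series(jit), cfg,
                                 max_lag = 4)
  expect_true(all(ac2$static))
  expect_true(all(ac2$rho == 1))
  ocds2 <- compute_ocds(ac2, metric_config(db_floor = 1e-15,
                                           ocds_window = c(204.8, 819.2)))
  expect_equal(max(abs(ocds2$values)), 0)
})

test_that("OCDS fits the late-window slope with the positive-speed sign", {
  cfg <- metric_config()
  # exact line rho = 1 - 1e-4 tau over the default window -> 1e-4 / ms
  curve <- tibble::tibble(delay_ms = seq(0, 1433.6, by = 204.8))
  curve$rho <- 1 - 1e-4 * curve$delay_ms
  expect_equal(compute_ocds(curve, cfg), 1e-4, tolerance = 1e-9)
  expect_equal(compute_ocds(curve, metric_config(ocds_sign = "raw_slope")),
               -1e-4, tolerance = 1e-9)
  # windows that select fewer than 2 lags are configuration errors
  expect_error(metric_config(ocds_window = c(500, 400)), "upper bound")
  expect_error(
    compute_ocds(curve, metric_config(ocds_window = c(204.8, 300))),
    "fewer than 2")
  # window below one frame interval is rejected at use
  p <- tiny_protocol(n_repeats = 10)
  s <- make_series(p, function(i, d, w) rlnorm(10))
  expect_error(
    compute_autocorrelation(s, metric_config(ocds_window = c(100, 1228.8))),
    "below one frame interval")
})

test_that("dynamics contrasts are invariant to linear intensity rescaling", {
  p <- tiny_protocol(n_loc = 2, n_repeats = 16, depth = 6, lateral = 6)
  set.seed(33)
  series <- make_series(p, function(i, d, w) rexp(16))
  ref <- compute_dynamics(series)  # auto floor scales with the mean
  for (c_scale in c(1e-2, 1e3)) {
    scaled <- frame_timeseries(series$intensity * c_scale, p)
    dyn <- compute_dynamics(scaled)
    expect_equal(dyn$liv$values, ref$liv$values, tolerance = 1e-10)
    expect_equal(dyn$ocds$values, ref$ocds$values, tolerance = 1e-10)
    # mean dB shifts by exactly 10 log10(c)
    expect_equal(dyn$liv$mean_intensity_db - ref$liv$mean_intensity_db,
                 array(10 * log10(c_scale), dim = dim(ref$liv$values)),
                 tolerance = 1e-9)
  }
})

test_that("LIV is non-negative and simulated OCDS matches the pooled-curve route", {
  p <- scan_protocol(n_blocks = 1, locations_per_block = 4, n_repeats = 32,
                     a_lines_per_frame = 24, n_depth_pixels = 24,
                     depth_pixel_size = 10)
  s <- simulate_uniform(p, m = 0.7, tau_c = 900, seed = 41)
  dyn <- compute_dynamics(s)
  expect_true(all(dyn$liv$values >= 0))
  # the per-voxel OCDS mean and the OCDS of the pooled per-voxel mean curve
  # agree (same lags, same OLS): internal consistency of the two code paths
  ac <- compute_autocorrelation(s, metric_config())
  mean_curve <- tibble::tibble(
    delay_ms = c(0, ac$delays), rho = c(1, colMeans(ac$rho)))
  expect_equal(mean(dyn$ocds$values), compute_ocds(mean_curve, metric_config()),
               tolerance = 1e-8)
})
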