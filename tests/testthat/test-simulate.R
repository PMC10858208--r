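test_that("static regions repeat identically without noise", {
  p <- tiny_protocol(n_loc = 2, n_repeats = 6, depth = 8, lateral = 8)
  s <- simulate_uniform(p, m = 0, tau_c = 1000, seed = 5)
  for (r in 2:6) {
    expect_equal(s$intensity[, r, , ], s$intensity[, 1, , ])
  }
})

test_that("fully developed fast speckle is exponentially distributed", {
  # m = 1, tau_c << frame interval: i.i.d. samples; Siegert limit
  p <- scan_protocol(n_blocks = 1, locations_per_block = 4, n_repeats = 32,
                     a_lines_per_frame = 40, n_depth_pixels = 40,
                     depth_pixel_size = 10)
  s <- simulate_uniform(p, m = 1, tau_c = 1, seed = 6)
  set.seed(60)
  draws <- sample(as.vector(s$intensity), 5000)
  ks <- suppressWarnings(stats::ks.test(draws, "pexp", rate = 1))
  expect_gt(ks$p.value, 0.01)
  # mean intensity equals the region reflectivity
  expect_lt(abs(mean(s$intensity) - 1), 0.02)
})

test_that("simulation is bit-identical under the same seed", {
  p <- tiny_protocol(n_loc = 2, n_repeats = 8, depth = 8, lateral = 8)
  ph <- build_phantom(phantom_spec(
    p, radii_um = c(5, 25, 30), center_vox = c(1.5, 4, 4.5),
    boundary_perturbation = 0.1, core_fraction = 0.4, plate_depth = 8,
    noise_floor = 1e-3, seed = 3))
  s1 <- simulate_timeseries(ph, p, seed = 9)
  s2 <- simulate_timeseries(ph, p, seed = 9)
  s3 <- simulate_timeseries(ph, p, seed = 10)
  expect_identical(s1$intensity, s2$intensity)
  expect_false(identical(s1$intensity, s3$intensity))
})

test_that("analytic Siegert curve obeys its algebraic limits", {
  d <- c(0, 204.8, 409.6, 819.2)
  expect_equal(analytic_intensity_correlation(0, 500, d)$rho, rep(1, 4))
  expect_equal(analytic_intensity_correlation(1, 500, d)$rho,
               exp(-2 * d / 500))
  expect_equal(analytic_intensity_correlation(0.3, 750, 0)$rho, 1)
  expect_error(analytic_intensity_correlation(0.3, 750, -1), "non-negative")
  # partially dynamic value computed from the stated formula
  expect_equal(analytic_intensity_correlation(0.5, 409.6, 409.6)$rho,
               (0.5 + 0.5 * exp(-1))^2)
})

test_that("Monte-Carlo pooled correlation matches the Siegert oracle at m = 0.5", {
  # >= 1e5 voxel realisations, single in-window delay 409.6 ms (lag 2)
  p <- scan_protocol(n_blocks = 1, locations_per_block = 7, n_repeats = 32,
                     a_lines_per_frame = 122, n_depth_pixels = 122,
                     depth_pixel_size = 10)
  s <- simulate_uniform(p, m = 0.5, tau_c = 409.6, seed = 14)
  curve <- pooled_autocorrelation(s, max_lag = 2, domain = "linear")
  expected <- (0.5 + 0.5 * exp(-1))^2
  expect_lt(abs(curve$rho[curve$delay_ms == 409.6] - expected), 0.015)
})

test_that("log-domain analytic curve quantifies the dB estimator bias", {
  # dilogarithm form: corr(ln I) = Li2(rho)/ (pi^2/6); check endpoints and
  # against a pooled dB-domain estimate for fully developed speckle
  expect_equal(analytic_intensity_correlation(1, 500, 0, "log_intensity")$rho, 1)
  p <- scan_protocol(n_blocks = 1, locations_per_block = 6, n_repeats = 32,
                     a_lines_per_frame = 64, n_depth_pixels = 64,
                     depth_pixel_size = 10)
  s <- simulate_uniform(p, m = 1, tau_c = 819.2, seed = 15)
  emp <- pooled_autocorrelation(s, max_lag = 4, domain = "db")
  an <- analytic_intensity_correlation(1, 819.2, emp$delay_ms,
                                       "log_intensity")
  expect_lt(max(abs(emp$rho - an$rho)), 0.02)
  expect_error(analytic_intensity_correlation(0.5, 500, 0, "log_intensity"),
               "m = 1")
})

test_that("patchy dead-cell draws hit the requested fraction in contiguous patches", {
  p <- scan_protocol(n_blocks = 1, locations_per_block = 8, n_repeats = 4,
                     a_lines_per_frame = 40, n_depth_pixels = 40,
                     depth_pixel_size = 10)
  ph <- uniform_label_volume(p, region_dynamics(1, 600, dead_fraction = 0.3),
                             seed = 2)
  s <- simulate_timeseries(ph, p, seed = 2)
  # dead voxels are exactly static: zero temporal variance without noise
  v <- apply(s$intensity, c(1, 3, 4), var)
  frac_static <- mean(v < 1e-20)
  expect_equal(frac_static, 0.3, tolerance = 0.01)
  # patchiness: a static voxel's 6-neighbourhood is mostly static too
  static <- v < 1e-20
  idx <- which(static, arr.ind = TRUE)
  idx <- idx[idx[, 2] > 1 & idx[, 2] < 40, , drop = FALSE]
  neigh <- static[cbind(idx[, 1], idx[, 2] + 1, idx[, 3])]
  expect_gt(mean(neigh), 0.7)
})
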