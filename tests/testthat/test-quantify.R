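flat_mask <- function(dims, n_true) {
  m <- array(FALSE, dim = dims)
  m[seq_len(n_true)] <- TRUE
  m
}

mk_vol <- function(values, metric = "LIV") {
  doct:::new_dynamics_volume(values, metric,
                             if (metric == "LIV") "dB^2" else "1/ms",
                             array(0, dim = dim(values)), tiny_protocol())
}

test_that("volume is voxel count times voxel volume", {
  m <- flat_mask(c(10, 10, 10), 1000)
  expect_equal(compute_volume(m, voxel_volume_mm3 = 1e-6), 1e-3)
  expect_equal(compute_volume(array(FALSE, c(4, 4, 4)),
                              voxel_volume_mm3 = 1e-6), 0)
  expect_error(compute_volume(m), "voxel volume")
})

test_that("mean metrics average the in-mask voxels", {
  dims <- c(4, 4, 4)
  m <- flat_mask(dims, 32)
  liv <- mk_vol(array(5, dims))
  ocds_vals <- array(0, dims)
  ocds_vals[seq_len(16)] <- 1e-4
  ocds_vals[17:32] <- 3e-4
  ocds <- mk_vol(ocds_vals, "OCDS_l")
  mm <- mean_metrics(m, liv, ocds)
  expect_equal(mm$mean_liv, 5)
  expect_equal(mm$mean_ocds, 2e-4)
  expect_error(mean_metrics(array(FALSE, dims), liv, ocds), "empty")
})

test_that("mixed-region mean equals the voxel-count-weighted region means", {
  dims <- c(6, 6, 6)
  vals <- array(0, dims)
  region <- array(rep(c(1L, 2L), c(150, 66)), dims)
  vals[region == 1L] <- 1.5   # low-motility core level
  vals[region == 2L] <- 24    # viable shell level
  liv <- mk_vol(vals)
  m <- array(TRUE, dims)
  expected <- (150 * 1.5 + 66 * 24) / 216  # direct weighted mean
  expect_equal(mean_metrics(m, liv, mk_vol(vals, "OCDS_l"))$mean_liv,
               expected)
})

test_that("dead-cell ratios count strict sub-cutoff voxels", {
  dims <- c(5, 5, 4)
  m <- array(TRUE, dims)
  liv_all_live <- mk_vol(array(10, dims))
  expect_equal(dead_cell_ratio(m, liv_all_live), 0)
  # exactly 30% of in-mask voxels below the cut-off
  vals <- array(10, dims)
  vals[seq_len(30)] <- 1
  expect_equal(dead_cell_ratio(m, mk_vol(vals)), 0.30)
  # strictness: values equal to the cut-off are alive
  vals_eq <- array(3, dims)
  expect_equal(dead_cell_ratio(m, mk_vol(vals_eq)), 0)
  # complement identity
  r <- dead_cell_ratio(m, mk_vol(vals))
  expect_equal(r + mean(vals[m] >= 3), 1)
  # OCDS volumes use the OCDS cut-off
  ov <- array(3e-4, dims); ov[1:10] <- 1e-4
  expect_equal(dead_cell_ratio(m, mk_vol(ov, "OCDS_l")), 0.1)
  expect_error(dead_cell_ratio(array(FALSE, dims), liv_all_live), "empty")
})

test_that("Welch test handles the degenerate and textbook cases", {
  same <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  const <- welch_ttest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(const$t, 0)
  expect_equal(const$p, 1)
  sep <- welch_ttest(c(0, 0, 0), c(1, 1, 1))
  expect_equal(sep$p, 0)
  expect_true(is.infinite(sep$t))
  # p -> 0 as within-group variance vanishes
  p_eps <- vapply(c(1e-2, 1e-4, 1e-6), function(eps) {
    welch_ttest(c(0, eps, -eps), c(1, 1 + eps, 1 - eps))$p
  }, numeric(1))
  expect_true(all(diff(p_eps) < 0))
  expect_lt(p_eps[3], 1e-10)
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
})

test_that("Welch test matches the Satterthwaite formulas on random groups", {
  set.seed(81)
  for (i in 1:100) {
    a <- rnorm(sample(2:6, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:6, 1), mean = runif(1, -1, 1))
    got <- welch_ttest(a, b)
    want <- brute_welch(a, b)
    expect_equal(got$t, unname(want["t"]), tolerance = 1e-10)
    expect_equal(got$dof, unname(want["dof"]), tolerance = 1e-10)
    expect_equal(got$p, unname(want["p"]), tolerance = 1e-10)
  }
})

test_that("quantify_spheroid assembles all scalars coherently", {
  dims <- c(5, 5, 4)
  m <- structure(list(mask = array(TRUE, dims), voxel_volume_mm3 = 1e-6,
                      threshold_db = -10, plate_depth = NA_integer_,
                      config = segmentation_config()),
                 class = "segmentation_mask")
  vals <- array(10, dims); vals[1:30] <- 1
  ov <- array(3e-4, dims); ov[1:10] <- 1e-4
  row <- quantify_spheroid(m, mk_vol(vals), mk_vol(ov, "OCDS_l"))
  expect_equal(row$volume_mm3, 100e-6)
  expect_equal(row$dead_ratio_liv, 0.3)
  expect_equal(row$dead_ratio_ocds, 0.1)
  expect_equal(row$n_voxels, 100L)
})
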