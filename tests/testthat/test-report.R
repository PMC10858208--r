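# Small synthetic per-spheroid table with known trends and no noise.
fake_spheroids <- function(drugs = c("control", "TAM"),
                           concs = c(0, 10), reps = 3, noise = 0) {
  rows <- list()
  for (i in seq_along(drugs)) {
    for (day in c(1, 3, 6)) {
      for (r in seq_len(reps)) {
        growth <- if (drugs[i] == "control") day else -day
        rows[[length(rows) + 1L]] <- tibble::tibble(
          drug = drugs[i], concentration_uM = concs[i], treatment_day = day,
          replicate = r,
          volume_mm3 = 0.01 + 0.001 * growth + noise * (r - 2),
          mean_liv = 20 - (if (drugs[i] == "control") 0 else 2 * day),
          mean_ocds = 4e-4 - (if (drugs[i] == "control") 0 else 4e-5 * day),
          dead_ratio_liv = 0.1 + (if (drugs[i] == "control") 0 else 0.08 * day),
          dead_ratio_ocds = 0.2 + (if (drugs[i] == "control") 0 else 0.05 * day))
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("report dimensions follow conditions x days x metrics", {
  rep_obj <- timecourse_report(fake_spheroids())
  expect_s3_class(rep_obj, "doct_report")
  # summary: 2 conditions x 3 days x 5 metrics
  expect_equal(nrow(rep_obj$summary), 2 * 3 * 5)
  # comparisons: 2 conditions x 3 day pairs x 5 metrics
  expect_equal(nrow(rep_obj$comparisons), 2 * 3 * 5)
  expect_setequal(unique(paste(rep_obj$comparisons$day_a,
                               rep_obj$comparisons$day_b)),
                  c("1 3", "3 6", "1 6"))
  g <- glance(rep_obj)
  expect_equal(g$n_spheroids, 18L)
  expect_equal(g$n_conditions, 2L)
  expect_identical(tidy(rep_obj), rep_obj$comparisons)
})

test_that("identical replicates give zero-width error bars", {
  rep_obj <- timecourse_report(fake_spheroids(noise = 0))
  expect_true(all(rep_obj$summary$sd == 0))
  # and nonzero replicate spread propagates
  rep2 <- timecourse_report(fake_spheroids(noise = 1e-4))
  vols <- dplyr::filter(rep2$summary, metric == "volume_mm3")
  expect_true(all(vols$sd > 0))
})

test_that("conditions with missing replicates are skipped with a warning", {
  tbl <- fake_spheroids()
  tbl <- tbl[!(tbl$drug == "TAM" & tbl$treatment_day == 6 &
                 tbl$replicate > 1), ]
  ws <- testthat::capture_warnings(rep_obj <- timecourse_report(tbl))
  expect_true(all(grepl("fewer than 2 replicates", ws)))
  expect_length(ws, 10L)  # 5 metrics x 2 day pairs involving day 6
  # the TAM day-6 comparisons are absent, the rest are intact
  tam6 <- dplyr::filter(rep_obj$comparisons, drug == "TAM", day_b == 6)
  expect_equal(nrow(tam6), 0L)
  ctrl <- dplyr::filter(rep_obj$comparisons, drug == "control")
  expect_equal(nrow(ctrl), 15L)
})

test_that("missing columns are rejected", {
  expect_error(timecourse_report(tibble::tibble(drug = "x")),
               "lacks columns")
})

test_that("autoplot returns a ggplot of the requested metric", {
  rep_obj <- timecourse_report(fake_spheroids(noise = 1e-4))
  p <- ggplot2::autoplot(rep_obj, metric = "mean_liv")
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_timecourse(rep_obj, "dead_ratio_liv"), "ggplot")
  expect_error(ggplot2::autoplot(rep_obj, metric = "nope"))
})

test_that("expectation evaluation detects matching and violated directions", {
  rep_obj <- timecourse_report(fake_spheroids())
  exp_tbl <- tibble::tibble(
    drug = c("control", "TAM", "TAM", "TAM"),
    concentration_uM = c(0, 10, 10, 10),
    metric = c("volume_mm3", "volume_mm3", "mean_liv", "dead_ratio_liv"),
    day_a = 1, day_b = 6,
    direction = c("up", "down", "down", "up"))
  ev <- evaluate_expectations(rep_obj, exp_tbl)
  expect_true(all(ev$pass))
  # flipping a direction flips the verdict
  exp_tbl$direction[1] <- "down"
  expect_false(evaluate_expectations(rep_obj, exp_tbl)$pass[1])
  # unknown condition yields a clean failure row, not an error
  exp_missing <- exp_tbl[1, ]
  exp_missing$drug <- "PTX"
  expect_false(evaluate_expectations(rep_obj, exp_missing)$pass)
})

test_that("the shipped expectation table covers the study patterns", {
  tbl <- study_expectations()
  expect_true(all(tbl$direction %in% c("up", "down")))
  expect_true(all(tbl$metric %in% c("volume_mm3", "mean_liv", "mean_ocds",
                                    "dead_ratio_liv", "dead_ratio_ocds")))
  # TAM 10 uM volume is judged on the day-3 -> day-6 collapse
  tam10 <- dplyr::filter(tbl, drug == "TAM", concentration_uM == 10,
                         metric == "volume_mm3")
  expect_equal(tam10$day_a, 3)
  expect_equal(tam10$direction, "down")
})
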