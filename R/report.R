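report_metrics <- c("volume_mm3", "mean_liv", "mean_ocds",
                    "dead_ratio_liv", "dead_ratio_ocds")

#' Summarise a spheroid study into trends and day comparisons
#'
#' Takes the per-spheroid scalar table (one row per spheroid, as produced by
#' [run_study()] / [quantify_spheroid()]) and computes, per condition
#' (drug x concentration) and treatment day, the replicate mean and standard
#' deviation of each scalar, plus all pairwise day comparisons (day 1 vs 3,
#' 3 vs 6, 1 vs 6) per condition via [welch_ttest()] on the replicate
#' values. No multiple-testing correction is applied; p-values are reported
#' raw. Conditions with fewer than 2 replicates on a day are omitted from
#' comparisons with a warning.
#'
#' @param spheroids Tibble with columns `drug`, `concentration_uM`,
#'   `treatment_day`, `replicate` and the scalar columns `volume_mm3`,
#'   `mean_liv`, `mean_ocds`, `dead_ratio_liv`, `dead_ratio_ocds`.
#' @return A `doct_report`: list with tibbles `spheroids`, `summary`
#'   (condition x day x metric mean/sd/n) and `comparisons` (condition x
#'   metric x day pair with `t`, `dof`, `p`).
#' @export
timecourse_report <- function(spheroids) {
  stopifnot(is.data.frame(spheroids))
  need <- c("drug", "concentration_uM", "treatment_day", "replicate",
            report_metrics)
  missing_cols <- setdiff(need, names(spheroids))
  if (length(missing_cols)) {
    stop_doct("spheroid table lacks columns: %s",
              paste(missing_cols, collapse = ", "))
  }
  spheroids <- as_tibble(spheroids)
  long <- tidyr::pivot_longer(spheroids, all_of(report_metrics),
                              names_to = "metric", values_to = "value")
  summary <- long %>%
    group_by(.data$drug, .data$concentration_uM, .data$treatment_day,
             .data$metric) %>%
    summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
              n = dplyr::n(), .groups = "drop")

  days <- sort(unique(spheroids$treatment_day))
  pairs <- if (length(days) >= 2) {
    utils::combn(days, 2, simplify = FALSE)
  } else {
    list()
  }
  conditions <- distinct(spheroids, .data$drug, .data$concentration_uM)
  comparisons <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    sub <- filter(long, .data$drug == cond$drug,
                  .data$concentration_uM == cond$concentration_uM)
    for (pair in pairs) {
      a <- filter(sub, .data$treatment_day == pair[1])
      b <- filter(sub, .data$treatment_day == pair[2])
      for (met in report_metrics) {
        va <- a$value[a$metric == met]
        vb <- b$value[b$metric == met]
        if (length(va) < 2L || length(vb) < 2L) {
          warn(sprintf("skipping %s %g uM %s day %g vs %g: fewer than 2 replicates",
                       cond$drug, cond$concentration_uM, met, pair[1], pair[2]))
          next
        }
        wt <- welch_ttest(va, vb)
        comparisons[[length(comparisons) + 1L]] <- tibble(
          drug = cond$drug, concentration_uM = cond$concentration_uM,
          metric = met, day_a = pair[1], day_b = pair[2],
          mean_a = mean(va), mean_b = mean(vb),
          t = wt$t, dof = wt$dof, p = wt$p)
      }
    }
  }
  structure(
    list(spheroids = spheroids, summary = summary,
         comparisons = bind_rows(comparisons)),
    class = "doct_report"
  )
}

#' @export
print.doct_report <- function(x, ...) {
  cat(sprintf("<doct_report> %d spheroids, %d conditions, %d day comparisons\n",
              nrow(x$spheroids),
              nrow(distinct(x$spheroids, .data$drug, .data$concentration_uM)),
              nrow(x$comparisons)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the group comparisons of a study report
#'
#' @param x A `doct_report`.
#' @param ... Unused.
#' @return The `comparisons` tibble (one row per condition x metric x day
#'   pair: Welch `t`, `dof`, two-sided `p`).
#' @export
tidy.doct_report <- function(x, ...) x$comparisons

#' One-row overview of a study report
#'
#' @param x A `doct_report`.
#' @param ... Unused.
#' @return A one-row tibble: spheroid, condition, day and comparison counts.
#' @export
glance.doct_report <- function(x, ...) {
  tibble(
    n_spheroids = nrow(x$spheroids),
    n_conditions = nrow(distinct(x$spheroids, .data$drug,
                                 .data$concentration_uM)),
    n_days = length(unique(x$spheroids$treatment_day)),
    n_comparisons = nrow(x$comparisons)
  )
}

#' Plot time courses of a study scalar
#'
#' Replicate mean with +/- one standard-deviation error bars versus
#' treatment day, coloured by concentration and facetted by drug.
#'
#' @param object A `doct_report`.
#' @param metric One of `"volume_mm3"`, `"mean_liv"`, `"mean_ocds"`,
#'   `"dead_ratio_liv"`, `"dead_ratio_ocds"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.doct_report <- function(object, metric = "volume_mm3", ...) {
  stopifnot(metric %in% report_metrics)
  dat <- filter(object$summary, .data$metric == !!metric)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$treatment_day, y = .data$mean,
    colour = factor(.data$concentration_uM),
    group = factor(.data$concentration_uM))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::facet_wrap(~drug) +
    ggplot2::labs(x = "treatment day", y = metric, colour = "conc (uM)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.doct_report
#' @param report A `doct_report`.
#' @export
plot_timecourse <- function(report, metric = "volume_mm3") {
  autoplot.doct_report(report, metric = metric)
}

#' Expected direction of day-over-day changes per condition
#'
#' The qualitative drug-response pattern the synthetic study emulates, as a
#' sign-expectation table on replicate means: growth of untreated and
#' low-dose TAM spheroids; TAM 10 uM volume collapse after day 3; PTX and
#' DOX 1 uM shrinkage versus DOX 10 uM swelling; and, under the effective
#' treatments, monotone decline of mean LIV and OCDS_l with a rise of both
#' dead-cell ratios.
#'
#' @return Tibble with columns `drug`, `concentration_uM`, `metric`,
#'   `day_a`, `day_b`, `direction` (`"up"`/`"down"`, day_a -> day_b).
#' @export
study_expectations <- function() {
  vol <- tibble(
    drug = c("control", "TAM", "TAM", "TAM", "PTX", "PTX", "DOX", "DOX"),
    concentration_uM = c(0, 0.1, 1, 10, 1, 10, 1, 10),
    metric = "volume_mm3",
    day_a = c(1, 1, 1, 3, 1, 1, 1, 1),
    day_b = 6,
    direction = c("up", "up", "up", "down", "down", "down", "down", "up")
  )
  effective <- tibble(drug = c("TAM", "PTX", "PTX", "DOX", "DOX"),
                      concentration_uM = c(10, 1, 10, 1, 10))
  dyn <- tidyr::expand_grid(
    effective,
    metric = c("mean_liv", "mean_ocds", "dead_ratio_liv", "dead_ratio_ocds")
  ) %>%
    mutate(day_a = 1, day_b = 6,
           direction = ifelse(grepl("^dead", .data$metric), "up", "down"))
  bind_rows(vol, dyn)
}

#' Check a study report against a sign-expectation table
#'
#' For each expected direction, compares the replicate means of the metric at
#' the two days and records whether the observed change has the expected
#' sign.
#'
#' @param report A `doct_report`.
#' @param expectations Tibble as returned by [study_expectations()].
#' @return The expectation tibble with `mean_a`, `mean_b`, `observed`
#'   (`"up"`/`"down"`) and `pass` columns.
#' @export
evaluate_expectations <- function(report, expectations = study_expectations()) {
  stopifnot(inherits(report, "doct_report"))
  rows <- pmap(expectations, function(drug, concentration_uM, metric,
                                      day_a, day_b, direction) {
    s <- filter(report$summary, .data$drug == !!drug,
                .data$concentration_uM == !!concentration_uM,
                .data$metric == !!metric,
                .data$treatment_day %in% c(day_a, day_b))
    if (nrow(s) != 2L) {
      return(tibble(mean_a = NA_real_, mean_b = NA_real_,
                    observed = NA_character_, pass = FALSE))
    }
    ma <- s$mean[s$treatment_day == day_a]
    mb <- s$mean[s$treatment_day == day_b]
    obs <- if (mb > ma) "up" else "down"
    tibble(mean_a = ma, mean_b = mb, observed = obs,
           pass = obs == direction)
  })
  dplyr::bind_cols(expectations, bind_rows(rows))
}
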