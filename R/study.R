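#' Enumerate the spheroids of a drug-treatment study design
#'
#' Builds the full cross product of drugs, concentrations, treatment days and
#' replicates, plus one untreated control group (concentration 0) per
#' treatment day and replicate. The default design is the standard one:
#' 3 drugs (TAM, PTX, DOX) x 3 concentrations (0.1, 1, 10 uM) + control =
#' 10 groups, 3 replicates, treatment days 1, 3 and 6 - 90 spheroids in
#' total, 30 per treatment day. The study is cross-sectional: each row is a
#' distinct spheroid.
#'
#' @param drugs Character vector of drug names.
#' @param concentrations_uM Numeric concentrations applied to every drug (uM).
#' @param treatment_days Integer treatment days at which spheroids are imaged.
#' @param n_replicates Spheroids per condition and day.
#' @param include_control Add an untreated (`"control"`, 0 uM) group, once per
#'   day x replicate (not per drug).
#' @return A tibble with columns `drug`, `concentration_uM`, `treatment_day`,
#'   `replicate`.
#' @examples
#' nrow(enumerate_study()) # 90
#' @export
enumerate_study <- function(drugs = c("TAM", "PTX", "DOX"),
                            concentrations_uM = c(0.1, 1, 10),
                            treatment_days = c(1, 3, 6),
                            n_replicates = 3,
                            include_control = TRUE) {
  stopifnot(length(drugs) >= 0, is.numeric(treatment_days))
  n_replicates <- assert_count(n_replicates, "n_replicates")
  if (anyDuplicated(drugs)) stop_doct("duplicated drug names in design")
  treated <- tidyr::expand_grid(
    drug = as.character(drugs),
    concentration_uM = as.numeric(concentrations_uM),
    treatment_day = as.numeric(treatment_days),
    replicate = seq_len(n_replicates)
  )
  out <- treated
  if (include_control) {
    control <- tidyr::expand_grid(
      drug = "control",
      concentration_uM = 0,
      treatment_day = as.numeric(treatment_days),
      replicate = seq_len(n_replicates)
    )
    out <- bind_rows(control, treated)
  }
  arrange(out, .data$treatment_day, .data$drug != "control", .data$drug,
          .data$concentration_uM, .data$replicate)
}
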