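#' Deterministic per-spheroid seed fan-out
#'
#' Maps `(master_seed, drug, concentration, day, replicate)` to a stable
#' 31-bit seed via a fixed condition code, so adding conditions to a design
#' never changes the data of existing spheroids.
#'
#' @param master_seed Integer master seed of the run.
#' @param drug,concentration_uM,treatment_day,replicate Condition labels.
#' @return A single integer seed.
#' @export
spheroid_seed <- function(master_seed, drug, concentration_uM, treatment_day,
                          replicate) {
  drug_id <- match(drug, c("control", "TAM", "PTX", "DOX")) - 1L
  if (is.na(drug_id)) drug_id <- sum(utf8ToInt(drug)) %% 13L + 4L
  conc_id <- match(concentration_uM, c(0, 0.1, 1, 10)) - 1L
  if (is.na(conc_id)) conc_id <- as.integer(round(concentration_uM * 10)) %% 29L + 4L
  day_id <- as.integer(round(treatment_day))
  code <- ((drug_id * 32L + conc_id) * 16L + day_id) * 64L + as.integer(replicate)
  as.integer((abs(as.integer(master_seed)) %% 65011L) * 33013L + code * 101L) %% 2147483647L
}

#' Configuration of an end-to-end synthetic study run
#'
#' @param protocol A [scan_protocol()] (default [study_protocol()]).
#' @param metric_config A [metric_config()].
#' @param segmentation A [segmentation_config()].
#' @param cutoffs A [viability_cutoffs()].
#' @param colormaps Named list of [colormap_spec()]s for `LIV` and `OCDS_l`.
#' @param design Study design tibble from [enumerate_study()].
#' @param table A [scenario_table()].
#' @param master_seed Integer master seed; all per-spheroid seeds derive
#'   from it via [spheroid_seed()].
#' @param output_root Directory for artifacts, or `NULL` (default) to keep
#'   the run in memory only.
#' @return A `run_config` object.
#' @export
run_config <- function(protocol = study_protocol(),
                       metric_config = doct::metric_config(),
                       segmentation = segmentation_config(),
                       cutoffs = viability_cutoffs(),
                       colormaps = list(LIV = default_colormap("LIV"),
                                        OCDS_l = default_colormap("OCDS_l")),
                       design = enumerate_study(),
                       table = scenario_table(),
                       master_seed = 1,
                       output_root = NULL) {
  stopifnot(is_scan_protocol(protocol), is_metric_config(metric_config),
            is_segmentation_config(segmentation),
            inherits(cutoffs, "viability_cutoffs"),
            inherits(table, "scenario_table"), is.data.frame(design))
  structure(
    list(protocol = protocol, metric_config = metric_config,
         segmentation = segmentation, cutoffs = cutoffs,
         colormaps = colormaps, design = design, table = table,
         master_seed = as.integer(master_seed), output_root = output_root),
    class = "run_config"
  )
}

spheroid_tag <- function(drug, conc, day, rep) {
  sprintf("%s_%s_TD%d_r%d", drug, gsub("[.]", "p", format(conc)), day, rep)
}

process_one_spheroid <- function(cfg, drug, conc, day, rep,
                                 write_artifacts = FALSE, write_raw = FALSE) {
  seed <- spheroid_seed(cfg$master_seed, drug, conc, day, rep)
  spec <- scenario_spec(drug, conc, day, replicate_seed = seed,
                        protocol = cfg$protocol, table = cfg$table)
  regions <- build_phantom(spec)
  series <- simulate_timeseries(regions, cfg$protocol, seed = seed + 1L)
  dyn <- compute_dynamics(series, cfg$metric_config)
  mask <- segment_spheroid(dyn$liv, cfg$segmentation, protocol = cfg$protocol)
  row <- quantify_spheroid(mask, dyn$liv, dyn$ocds, cfg$cutoffs)
  row <- dplyr::bind_cols(
    tibble(drug = drug, concentration_uM = conc, treatment_day = day,
           replicate = rep, seed = seed,
           threshold_db = mask$threshold_db),
    row)
  if (write_artifacts && !is.null(cfg$output_root)) {
    dir <- file.path(cfg$output_root, "spheroids",
                     spheroid_tag(drug, conc, day, rep))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (write_raw) write_timeseries(series, file.path(dir, "raw"))
    write_metric_volume(dyn$liv, file.path(dir, "liv"))
    write_metric_volume(dyn$ocds, file.path(dir, "ocds"))
    for (what in c("liv", "ocds")) {
      vol <- dyn[[what]]
      rgb <- compose_pseudocolor(vol, cfg$colormaps[[vol$metric]])
      dz <- center_depth(mask); lx <- center_location(mask)
      meta <- list(metric = vol$metric,
                   metric_range = cfg$colormaps[[vol$metric]]$metric_range,
                   intensity_range_db = cfg$colormaps[[vol$metric]]$intensity_range_db)
      render_slice_png(extract_en_face(rgb, dz),
                       file.path(dir, sprintf("%s_enface_d%03d.png", what, dz)),
                       c(meta, plane = "enface", index = dz))
      render_slice_png(extract_cross_section(rgb, lx),
                       file.path(dir, sprintf("%s_bscan_l%03d.png", what, lx)),
                       c(meta, plane = "bscan", index = lx))
    }
  }
  row
}

#' Run the full synthetic drug-response study
#'
#' For every spheroid in the design: derive its seed, build the scenario
#' phantom, simulate the speckle time series, compute LIV and OCDS_l,
#' segment the spheroid, and quantify volume, mean dynamics and dead-cell
#' ratios; then summarise everything with [timecourse_report()]. The run is
#' a pure function of `(config, master_seed)`. When `cfg$output_root` is
#' set, per-spheroid metric volumes and centre-plane pseudo-color PNGs, the
#' report CSVs and a manifest (versions, seeds, configuration) are written
#' there; raw time series are written only with `write_raw = TRUE` (they
#' dominate disk use).
#'
#' @param cfg A [run_config()].
#' @param write_raw Also write each spheroid's raw TIFF time series.
#' @param progress Print one line per spheroid.
#' @return A `doct_report` (see [timecourse_report()]); the per-spheroid
#'   table carries the seed and segmentation threshold actually used.
#' @export
run_study <- function(cfg = run_config(), write_raw = FALSE,
                      progress = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  write_artifacts <- !is.null(cfg$output_root)
  rows <- vector("list", nrow(cfg$design))
  for (i in seq_len(nrow(cfg$design))) {
    d <- cfg$design[i, ]
    if (progress) {
      message(sprintf("[%d/%d] %s %g uM day %g rep %d", i, nrow(cfg$design),
                      d$drug, d$concentration_uM, d$treatment_day,
                      d$replicate))
    }
    rows[[i]] <- process_one_spheroid(cfg, d$drug, d$concentration_uM,
                                      d$treatment_day, d$replicate,
                                      write_artifacts = write_artifacts,
                                      write_raw = write_raw)
  }
  report <- timecourse_report(bind_rows(rows))
  if (write_artifacts) {
    dir.create(cfg$output_root, recursive = TRUE, showWarnings = FALSE)
    write.csv(report$spheroids, file.path(cfg$output_root, "report.csv"),
              row.names = FALSE)
    write.csv(report$comparisons,
              file.path(cfg$output_root, "comparisons.csv"),
              row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("doct")),
      master_seed = cfg$master_seed,
      protocol = protocol_to_list(cfg$protocol),
      metric_config = unclass(cfg$metric_config),
      segmentation = unclass(cfg$segmentation),
      cutoffs = unclass(cfg$cutoffs),
      design_rows = nrow(cfg$design),
      seeds = report$spheroids$seed
    )
    jsonlite::write_json(manifest, file.path(cfg$output_root, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Write a dynamics volume as multi-page TIFF plus JSON sidecar
#'
#' Pages are B-scan locations; values are stored min-max normalised (32-bit
#' float) with the affine mapping recorded in the sidecar together with the
#' metric name and units. The mean-dB volume is written alongside.
#'
#' @param volume A `dynamics_volume`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_metric_volume <- function(volume, path) {
  stopifnot(is_dynamics_volume(volume))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_scaled_stack <- function(arr, file) {
    lo <- min(arr); hi <- max(arr)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(arr)[1]), function(i) (arr[i, , ] - lo) / scale)
    tiff::writeTIFF(pages, file, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    list(offset = lo, scale = scale)
  }
  map_values <- write_scaled_stack(volume$values, file.path(path, "values.tif"))
  map_db <- write_scaled_stack(volume$mean_intensity_db,
                               file.path(path, "mean_intensity_db.tif"))
  jsonlite::write_json(
    list(metric = volume$metric, units = volume$units,
         dims = dim(volume$values), values_map = map_values,
         mean_intensity_db_map = map_db,
         protocol = protocol_to_list(volume$protocol)),
    file.path(path, "volume.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' Read a dynamics volume written by [write_metric_volume()]
#'
#' @param path Directory with `values.tif`, `mean_intensity_db.tif`,
#'   `volume.json`.
#' @return A `dynamics_volume`.
#' @export
read_metric_volume <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "volume.json"),
                              simplifyVector = TRUE)
  read_stack <- function(file, map) {
    pages <- tiff::readTIFF(file, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = unlist(meta$dims))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * map$scale + map$offset
    arr
  }
  protocol <- protocol_from_list(meta$protocol)
  new_dynamics_volume(
    read_stack(file.path(path, "values.tif"), meta$values_map),
    meta$metric, meta$units,
    read_stack(file.path(path, "mean_intensity_db.tif"),
               meta$mean_intensity_db_map),
    protocol)
}
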