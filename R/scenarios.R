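#' Load the drug-scenario parameter table
#'
#' The scenario table is a versioned JSON file (one editable table, not code
#' constants) mapping each condition (drug x concentration) and treatment
#' day to phantom parameters: ellipsoid radii, necrotic-core fraction,
#' viable-shell dynamics, dead-voxel fraction, boundary corruption, and
#' drug-specific sub-regions (PTX low-dynamics spots and contiguous static
#' domains, DOX peripheral dead shell and concentric static ring). The
#' shipped table encodes the qualitative response patterns: untreated and
#' low-dose TAM growth, TAM 10 uM shape corruption and post-day-3 collapse,
#' PTX shrinkage with multiplying dead spots, DOX shrinkage at 1 uM versus
#' swelling at 10 uM with peripheral death - orderings only, not absolute
#' image values.
#'
#' @param path Path to a scenario JSON; default is the table shipped with
#'   the package.
#' @return A `scenario_table` (list with `defaults` and `scenarios`).
#' @export
scenario_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "scenario_table.json",
                                package = "doct", mustWork = TRUE)
  tab <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(tab$scenarios) || is.null(tab$defaults)) {
    stop_doct("scenario table %s lacks `scenarios`/`defaults`", path)
  }
  structure(tab, class = "scenario_table")
}

#' Conditions available in a scenario table
#'
#' @param table A [scenario_table()].
#' @return Tibble with `drug` and `concentration_uM`.
#' @export
scenario_conditions <- function(table = scenario_table()) {
  bind_rows(lapply(table$scenarios, function(s) {
    tibble(drug = s$drug, concentration_uM = as.numeric(s$concentration_uM))
  }))
}

num3 <- function(x) as.numeric(unlist(x))

find_scenario <- function(table, drug, concentration_uM) {
  for (s in table$scenarios) {
    if (identical(s$drug, drug) &&
        isTRUE(all.equal(as.numeric(s$concentration_uM),
                         as.numeric(concentration_uM)))) {
      return(s)
    }
  }
  stop_doct("no scenario for drug '%s' at %g uM", drug, concentration_uM)
}

dyn_from <- function(entry, dead_fraction = 0) {
  region_dynamics(m = entry$m, tau_c = entry$tau_c,
                  mean_reflectivity = entry$reflectivity,
                  dead_fraction = dead_fraction)
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Phantom specification for one study condition
#'
#' Resolves the scenario table for `(drug, concentration, day)` into a
#' [phantom_spec()]. Replicate individuality comes from `replicate_seed`: a
#' small multiplicative radius jitter (the table's
#' `replicate_radius_jitter`, default 3%), the random placement of spot and
#' domain sub-regions, the boundary-perturbation phase and the voxel-level
#' dead-cell draws all derive from it, so equal seeds give identical
#' phantoms.
#'
#' @param drug One of the drugs in the table (plus `"control"`).
#' @param concentration_uM Concentration in uM (0 for control).
#' @param treatment_day Treatment day present in the table (1, 3 or 6).
#' @param replicate_seed Integer seed for replicate-level randomness.
#' @param protocol A [scan_protocol()]; default [study_protocol()].
#' @param table A [scenario_table()].
#' @return A [phantom_spec()].
#' @export
scenario_spec <- function(drug, concentration_uM, treatment_day,
                          replicate_seed = 1, protocol = study_protocol(),
                          table = scenario_table()) {
  stopifnot(inherits(table, "scenario_table"))
  sc <- find_scenario(table, drug, concentration_uM)
  day <- sc$days[[as.character(treatment_day)]]
  if (is.null(day)) {
    stop_doct("scenario '%s' %g uM has no treatment day %s", drug,
              concentration_uM, format(treatment_day))
  }
  def <- table$defaults
  core_fraction <- day$core_fraction %||% 0
  radii <- num3(day$radii_um)
  overrides <- list()
  with_seed(replicate_seed, {
    jitter <- def$replicate_radius_jitter %||% 0
    radii <- radii * (1 + jitter * stats::runif(1, -1, 1))
    n_spots <- day$n_spots %||% 0
    if (n_spots > 0) {
      spot <- def$spot
      r_spot <- day$spot_radius_um %||% spot$radius_um
      for (j in seq_len(n_spots)) {
        rfrac <- stats::runif(1, min(core_fraction + 0.15, 0.6), 0.85)
        overrides[[length(overrides) + 1L]] <- list(
          name = sprintf("spot_%02d", j), type = "sphere",
          center_frac = random_unit_vector() * rfrac, radius_um = r_spot,
          dynamics = dyn_from(spot))
      }
    }
    n_domains <- day$n_domains %||% 0
    if (n_domains > 0) {
      dom <- def$domain
      r_dom <- day$domain_radius_um %||% dom$radius_um
      for (j in seq_len(n_domains)) {
        rfrac <- stats::runif(1, min(core_fraction + 0.2, 0.55), 0.7)
        overrides[[length(overrides) + 1L]] <- list(
          name = sprintf("domain_%02d", j), type = "sphere",
          center_frac = random_unit_vector() * rfrac, radius_um = r_dom,
          dynamics = dyn_from(dom))
      }
    }
  })
  if (!is.null(day$peripheral_thickness_um)) {
    overrides[[length(overrides) + 1L]] <- list(
      name = "peripheral_dead_shell", type = "shell",
      r_lo_frac = max(0, 1 - day$peripheral_thickness_um / mean(radii)),
      r_hi_frac = 1.4,
      dynamics = dyn_from(def$peripheral))
  }
  if (!is.null(day$ring)) {
    ring <- as.numeric(unlist(day$ring))
    overrides[[length(overrides) + 1L]] <- list(
      name = "static_ring", type = "shell",
      r_lo_frac = ring[1], r_hi_frac = ring[2],
      dynamics = dyn_from(def$ring))
  }
  shell <- region_dynamics(
    m = day$shell_m %||% def$shell$m,
    tau_c = day$shell_tau_c %||% def$shell$tau_c,
    mean_reflectivity = def$shell$reflectivity,
    dead_fraction = day$dead_fraction %||% 0)
  phantom_spec(
    protocol = protocol,
    radii_um = radii,
    boundary_perturbation = day$boundary_perturbation %||%
      def$boundary_perturbation %||% 0,
    core_fraction = core_fraction,
    shell = shell,
    core = dyn_from(def$core),
    region_overrides = overrides,
    plate_reflectivity = def$plate_reflectivity %||% 10,
    noise_floor = def$noise_floor %||% 1e-3,
    seed = as.integer(replicate_seed)
  )
}
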