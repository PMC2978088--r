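# Reading and writing the monitoring-record CSV schemas.

study_schemas <- function() {
  list(
    site_environment = readr::cols(
      site_id = readr::col_character(), watershed_id = readr::col_character(),
      reef_type = readr::col_integer(), shed_area_ha = readr::col_double(),
      disturbed_land_frac = readr::col_double(),
      wave_exposure = readr::col_double(), human_pop = readr::col_integer(),
      pig_pop = readr::col_integer()
    ),
    benthic_points = readr::cols(
      site_id = readr::col_character(), year = readr::col_integer(),
      transect = readr::col_integer(), frame = readr::col_integer(),
      dot = readr::col_integer(), category = readr::col_character(),
      genus = readr::col_character()
    ),
    coral_colonies = readr::cols(
      site_id = readr::col_character(), year = readr::col_integer(),
      transect = readr::col_integer(), quadrat = readr::col_integer(),
      species = readr::col_character(), d_max_cm = readr::col_double(),
      d_perp_cm = readr::col_double()
    ),
    quadrat_census = readr::cols(
      site_id = readr::col_character(), year = readr::col_integer(),
      transect = readr::col_integer(), quadrat = readr::col_integer()
    ),
    fish_spc = readr::cols(
      site_id = readr::col_character(), year = readr::col_integer(),
      replicate = readr::col_integer(), species = readr::col_character(),
      trophic_group = readr::col_character(),
      length_cm = readr::col_double(), count = readr::col_integer()
    ),
    invert_transects = readr::cols(
      site_id = readr::col_character(), year = readr::col_integer(),
      transect = readr::col_integer(), genus = readr::col_character(),
      count = readr::col_integer(), transect_area_m2 = readr::col_double()
    ),
    water_quality = readr::cols(
      watershed_id = readr::col_character(), date = readr::col_character(),
      constituent = readr::col_character(),
      concentration = readr::col_double()
    ),
    lw_params = readr::cols(
      species = readr::col_character(), A = readr::col_double(),
      B = readr::col_double()
    ),
    latent_truth = readr::cols(
      site_id = readr::col_character(), z_wq = readr::col_double(),
      z_herb = readr::col_double(), status_true = readr::col_double()
    )
  )
}

#' Write a study to a directory of CSV files
#'
#' One UTF-8, comma-separated file per table (`benthic_points.csv`,
#' `coral_colonies.csv`, `quadrat_census.csv`, `fish_spc.csv`,
#' `invert_transects.csv`, `water_quality.csv`, `site_environment.csv`,
#' `lw_params.csv`, and — for synthetic studies only — `latent_truth.csv`,
#' which downstream analysis must never consume), plus the scenario
#' configuration as `config.yaml`. Tables round-trip losslessly through
#' [read_study()].
#'
#' @param study A `reef_study`.
#' @param dir Target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, mode = 2) != 0) {
    abort(sprintf("cannot write to directory '%s'", dir))
  }
  for (nm in names(study_schemas())) {
    tab <- study[[nm]]
    if (!is.null(tab)) {
      readr::write_csv(tab, file.path(dir, paste0(nm, ".csv")), progress = FALSE)
    }
  }
  if (!is.null(study$config)) {
    yaml::write_yaml(unclass(study$config), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read a study back from a directory of CSV files
#'
#' Reads whichever schema files are present (see [write_study()]); missing
#' optional tables (`latent_truth`, `quadrat_census`, `config.yaml`) are
#' tolerated. When the quadrat census file is absent it is reconstructed
#' from the colony records (occupied quadrats only, so empty quadrats are
#' then unknown — supply the census to count them).
#'
#' @param dir Directory holding the CSV files.
#' @return A `reef_study` list.
#' @export
read_study <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("no such directory: '%s'", dir))
  schemas <- study_schemas()
  study <- list()
  for (nm in names(schemas)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(path)) {
      study[[nm]] <- readr::read_csv(path, col_types = schemas[[nm]],
                                     progress = FALSE)
    }
  }
  required <- c("site_environment", "benthic_points", "coral_colonies",
                "fish_spc", "invert_transects", "water_quality", "lw_params")
  missing <- setdiff(required, names(study))
  if (length(missing) > 0) {
    abort(sprintf("directory '%s' is missing required table(s): %s", dir,
                  paste(missing, collapse = ", ")))
  }
  if (is.null(study$quadrat_census)) {
    warn("no quadrat_census.csv: reconstructing census from occupied quadrats")
    study$quadrat_census <- dplyr::distinct(
      study$coral_colonies, .data$site_id, .data$year, .data$transect,
      .data$quadrat)
  }
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) {
    study$config <- read_scenario_config(cfg_path)
  }
  structure(study, class = "reef_study")
}
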