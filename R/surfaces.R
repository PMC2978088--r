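# Predicted-status surfaces over the water-quality x herbivory plane, and
# the end-to-end pipeline runner.

#' Interpolate predicted status over the stressor plane
#'
#' Evaluates a fitted model on a rectangular grid of water-quality and
#' herbivory values (standardized scores), yielding the contour surface of
#' predicted recovery status. The threshold contour — the hypothesized
#' boundary of favourable disturbance-recovery cycles — defaults to the
#' minimum status among sites classified "high" ([recovery_threshold()])
#' and can be overridden.
#'
#' @param model A `reef_model` whose terms use both stressor variables
#'   (directly or through a product term).
#' @param wq_range,herb_range Length-2 numeric ranges of the two axes.
#' @param resolution Grid nodes per axis (>= 2).
#' @param threshold Optional status threshold to store with the surface.
#' @param wq_var,herb_var Names of the stressor columns the model was fitted
#'   on; defaults `"z_wq_index"` and `"z_herbivory"`.
#' @return A tibble of class `reef_surface` with columns `wq`, `herb`,
#'   `predicted_status`; attributes `threshold`, `wq_var`, `herb_var`,
#'   `model_label`.
#' @export
build_surface <- function(model, wq_range = c(-2, 2), herb_range = c(-2, 2),
                          resolution = 41, threshold = NA_real_,
                          wq_var = "z_wq_index", herb_var = "z_herbivory") {
  if (!inherits(model, "reef_model")) abort("model must be a reef_model")
  if (resolution < 2) abort("resolution must be >= 2 grid nodes per axis")
  if (any(!is.finite(c(wq_range, herb_range)))) abort("axis ranges must be finite")
  used <- unique(unlist(purrr::map(model$terms, "vars")))
  if (!all(c(wq_var, herb_var) %in% used)) {
    abort(sprintf(
      "model must use both stressor variables ('%s', '%s'); it uses: %s",
      wq_var, herb_var, paste(used, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(
    wq = seq(wq_range[1], wq_range[2], length.out = resolution),
    herb = seq(herb_range[1], herb_range[2], length.out = resolution)
  )
  newdata <- tibble::tibble(!!wq_var := grid$wq, !!herb_var := grid$herb)
  grid$predicted_status <- as.numeric(predict(model, newdata))
  if (any(!is.finite(grid$predicted_status))) {
    abort("non-finite predictions on the grid; check term exponents vs axis ranges")
  }
  attr(grid, "threshold") <- threshold
  attr(grid, "wq_var") <- wq_var
  attr(grid, "herb_var") <- herb_var
  attr(grid, "model_label") <- model$label
  class(grid) <- c("reef_surface", class(grid))
  grid
}

# Stressor candidate set for the status regressions: each stressor alone,
# additive, and the replicate-crossed product.
stressor_candidates <- function(wq_var = "z_wq_index", herb_var = "z_herbivory") {
  list(
    "(null)" = list(),
    wq = list(pow_term(wq_var)),
    herbivory = list(pow_term(herb_var)),
    "wq + herbivory" = list(pow_term(wq_var), pow_term(herb_var)),
    "wq x herbivory" = list(pow_term(c(wq_var, herb_var))),
    "wq + herbivory + wq x herbivory" = list(
      pow_term(wq_var), pow_term(herb_var), pow_term(c(wq_var, herb_var)))
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a directory of monitoring CSVs or on a freshly
#' simulated study: site-year metrics, water-quality index, within-reef-type
#' standardization, status scores, recovery classification, stressor group
#' comparisons, species ordination, candidate regressions with AIC
#' selection, and the predicted-status surface. All outputs are written to
#' `out_dir` (`site_year_metrics.csv`, `wq_index.csv`, `status_scores.csv`,
#' `recovery_classification.csv`, `interaction_samples.csv`,
#' `ordination.csv`, `models.json`, `surface.csv`, `report.json`,
#' `run_log.txt`) and returned invisibly. Given the same config and seed the
#' run is deterministic.
#'
#' @param config A `reef_scenario` (simulated input), or NULL when
#'   `input_dir` is given.
#' @param out_dir Output directory.
#' @param input_dir Optional directory of monitoring CSVs to analyse
#'   instead of simulating.
#' @param seed Seed for the simulation; defaults to `config$seed`.
#' @param disturbance_year Year of the disturbance pulse; defaults to the
#'   config's, else the second survey year. Status is computed from
#'   post-disturbance rates of change.
#' @param surface_resolution Grid nodes per surface axis.
#' @return Invisibly, a list with elements `study`, `metrics`, `wq`,
#'   `site_table`, `status`, `classification`, `comparisons`, `ordination`,
#'   `models`, `surface`, `threshold`.
#' @export
run_pipeline <- function(config = scenario_config(), out_dir,
                         input_dir = NULL, seed = NULL,
                         disturbance_year = NULL, surface_resolution = 41) {
  if (!is.null(input_dir)) {
    study <- read_study(input_dir)
  } else {
    if (!is.null(seed)) {
      config$seed <- as.integer(seed)
      validate_scenario(config)
    }
    study <- generate_study(config)
  }
  ok <- dir.exists(out_dir) ||
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))

  # 1. site-year metrics from raw records
  metrics <- site_year_metrics(study)
  readr::write_csv(metrics, file.path(out_dir, "site_year_metrics.csv"),
                   progress = FALSE)

  # 2. water-quality index per watershed
  wq <- wq_index(study$water_quality)
  ranks_wide <- attr(wq, "ranks") |>
    tidyr::pivot_wider(names_from = "constituent", values_from = "rank",
                       names_prefix = "rank_")
  readr::write_csv(dplyr::left_join(wq, ranks_wide, by = "watershed_id"),
                   file.path(out_dir, "wq_index.csv"), progress = FALSE)

  # 3. site-based averages over all years (metric levels, for the
  #    environment regressions) plus post-disturbance rates of change in the
  #    two status metrics (recovery status tracks rates, not levels)
  dist_yr <- disturbance_year %||%
    (if (!is.null(study$config)) study$config$disturbance_year
     else sort(unique(metrics$year))[2])
  site_means <- metrics |>
    dplyr::summarise(
      coral_cover = mean(.data$coral_cover, na.rm = TRUE),
      richness_level = mean(.data$richness_per_quadrat, na.rm = TRUE),
      ratio_level = mean(.data$substrate_ratio, na.rm = TRUE),
      herbivory = mean(.data$herbivore_biomass, na.rm = TRUE),
      .by = "site_id"
    )
  yearly_rate <- function(y, x) {
    keep <- !is.na(y)
    if (sum(keep) < 3) return(NA_real_)
    unname(coef(lm(y[keep] ~ x[keep]))[2])
  }
  site_rates <- metrics |>
    dplyr::filter(.data$year >= dist_yr) |>
    dplyr::summarise(
      richness = yearly_rate(.data$richness_per_quadrat, .data$year),
      substrate_ratio = yearly_rate(.data$substrate_ratio, .data$year),
      .by = "site_id"
    )
  site_table <- study$site_environment |>
    dplyr::left_join(site_means, by = "site_id") |>
    dplyr::left_join(site_rates, by = "site_id") |>
    dplyr::left_join(wq, by = "watershed_id") |>
    dplyr::rename(wq_index = "index")
  bad_rate <- is.na(site_table$richness) | is.na(site_table$substrate_ratio)
  if (any(bad_rate)) {
    warn(sprintf(
      "site(s) without >= 3 post-disturbance surveys dropped from status analyses: %s",
      paste(site_table$site_id[bad_rate], collapse = ", ")))
    site_table <- site_table[!bad_rate, , drop = FALSE]
  }

  # drop reef types too small to standardize within
  type_n <- table(site_table$reef_type)
  small <- names(type_n)[type_n < 3]
  if (length(small) > 0) {
    inform(sprintf(
      "reef type(s) %s have < 3 sites and are excluded from standardized analyses",
      paste(small, collapse = ", ")))
  }
  strat <- dplyr::filter(site_table, !(.data$reef_type %in% as.integer(small)))

  # 4. status scores and standardized stressors (within reef type)
  status <- status_score(strat, reef_type)
  strat <- strat |>
    standardize(.data$wq_index, .data$reef_type, name = "z_wq_index") |>
    standardize(.data$herbivory, .data$reef_type, name = "z_herbivory")
  analysis <- dplyr::left_join(
    strat, dplyr::select(status, "site_id", "z_richness", "z_ratio", "status"),
    by = "site_id")
  readr::write_csv(
    dplyr::select(analysis, "site_id", "reef_type", "z_richness", "z_ratio",
                  "status", "z_wq_index", "z_herbivory"),
    file.path(out_dir, "status_scores.csv"), progress = FALSE)

  # 5. recovery classification: first vs last survey year, replicate level
  rich_q <- attr(metrics, "richness_quadrat")
  ratio_t <- attr(metrics, "ratio_transect")
  yr_pre <- min(metrics$year)
  yr_post <- max(metrics$year)
  classification <- purrr::map(unique(site_table$site_id), function(s) {
    rq <- dplyr::filter(rich_q, .data$site_id == s)
    rt <- dplyr::filter(ratio_t, .data$site_id == s,
                        !is.na(.data$substrate_ratio))
    pair_of <- function(df, value_col, rep_cols) {
      pre <- dplyr::filter(df, .data$year == yr_pre) |>
        dplyr::arrange(dplyr::pick(dplyr::all_of(rep_cols)))
      post <- dplyr::filter(df, .data$year == yr_post) |>
        dplyr::arrange(dplyr::pick(dplyr::all_of(rep_cols)))
      m <- min(nrow(pre), nrow(post))
      list(pre = pre[[value_col]][seq_len(m)],
           post = post[[value_col]][seq_len(m)])
    }
    pairs <- list(
      richness = pair_of(rq, "richness", c("transect", "quadrat")),
      substrate_ratio = pair_of(rt, "substrate_ratio", "transect")
    )
    cl <- tryCatch(classify_recovery(metric_pairs = pairs),
                   error = function(e) NULL)
    if (is.null(cl)) {
      return(tibble::tibble(site_id = s, category = "unclassified",
                            p_richness = NA_real_, p_ratio = NA_real_))
    }
    tibble::tibble(site_id = s, category = cl$category,
                   p_richness = cl$tests$p[cl$tests$metric == "richness"],
                   p_ratio = cl$tests$p[cl$tests$metric == "substrate_ratio"])
  }) |> purrr::list_rbind()
  readr::write_csv(classification, file.path(out_dir, "recovery_classification.csv"),
                   progress = FALSE)

  # 6. stressor comparison between recovery categories, replicate-crossed
  #    interaction samples per site
  biomass_rep <- attr(metrics, "biomass_replicate")
  interaction_samples <- purrr::map(analysis$site_id, function(s) {
    h <- biomass_rep$biomass_g[biomass_rep$site_id == s &
                                 biomass_rep$year == yr_post]
    shed <- analysis$watershed_id[analysis$site_id == s]
    w <- study$water_quality$concentration[
      study$water_quality$watershed_id == shed &
        study$water_quality$constituent == "Total_N"]
    if (length(h) < 2 || length(w) < 2) return(NULL)
    it <- interaction_term(as.vector(scale(h)), as.vector(scale(-w)))
    tibble::tibble(site_id = s, product = it$sample,
                   sample_mean = it$mean, sample_var = it$variance,
                   shapiro_p = it$shapiro_p)
  }) |> purrr::list_rbind()
  readr::write_csv(interaction_samples,
                   file.path(out_dir, "interaction_samples.csv"),
                   progress = FALSE)

  by_cat <- dplyr::left_join(analysis, classification, by = "site_id")
  comparisons <- NULL
  if (sum(by_cat$category == "high", na.rm = TRUE) >= 2 &&
      sum(by_cat$category == "low", na.rm = TRUE) >= 2) {
    comparisons <- purrr::map(
      c(wq_index = "z_wq_index", herbivory = "z_herbivory"),
      function(v) {
        compare_groups(by_cat[[v]][by_cat$category == "high"],
                       by_cat[[v]][by_cat$category == "low"])
      }) |>
      purrr::list_rbind(names_to = "variable")
    inter_site <- by_cat$z_wq_index * by_cat$z_herbivory
    comparisons <- dplyr::bind_rows(
      comparisons,
      dplyr::mutate(
        compare_groups(inter_site[by_cat$category == "high"],
                       inter_site[by_cat$category == "low"]),
        variable = "wq x herbivory"))
  }

  # 7. ordination of quadrat colony abundances (site-year x species)
  abundance <- study$coral_colonies |>
    dplyr::count(.data$site_id, .data$year, .data$species) |>
    tidyr::pivot_wider(names_from = "species", values_from = "n",
                       values_fill = 0) |>
    dplyr::mutate(id = paste(.data$site_id, .data$year, sep = ":")) |>
    dplyr::select(-"site_id", -"year")
  ordination <- species_centered_pca(abundance)
  ord_out <- dplyr::bind_rows(
    dplyr::mutate(tidyr::pivot_longer(ordination$scores, -"id",
                                      names_to = "axis"), kind = "score"),
    dplyr::mutate(tidyr::pivot_longer(ordination$loadings, -"species",
                                      names_to = "axis"),
                  kind = "loading", id = .data$species, species = NULL),
    tibble::tibble(kind = "var_explained",
                   axis = paste0("PC", seq_along(ordination$var_explained)),
                   id = "", value = ordination$var_explained)
  )
  readr::write_csv(ord_out, file.path(out_dir, "ordination.csv"),
                   progress = FALSE)

  # 8. candidate regressions and AIC selection
  stressors <- select_model(analysis, "status", stressor_candidates())
  env_vars <- c("shed_area_ha", "disturbed_land_frac", "wave_exposure",
                "human_pop", "pig_pop", "herbivory")
  # Table-1-style regressions predict metric levels from the environment
  env_models <- purrr::map(
    split(analysis, analysis$reef_type),
    function(d) {
      if (nrow(d) < 6) return(NULL)
      d <- dplyr::mutate(
        d, dplyr::across(dplyr::all_of(env_vars), function(x) pmax(x, 1e-6)))
      purrr::map(c(coral_cover = "coral_cover", status = "status"),
                 function(resp) {
                   tryCatch(
                     select_model(d, resp,
                                  enumerate_candidates(d, resp, env_vars)),
                     error = function(e) NULL)
                 })
    })

  best <- stressors$models[[stressors$table$model[1]]]
  surface_model <- if (all(c("z_wq_index", "z_herbivory") %in%
                           unlist(purrr::map(best$terms, "vars")))) {
    best
  } else {
    stressors$models[["wq x herbivory"]]
  }
  threshold <- recovery_threshold(status, classification)
  surface <- build_surface(surface_model, resolution = surface_resolution,
                           threshold = threshold)
  readr::write_csv(
    tibble::tibble(wq = surface$wq, herb = surface$herb,
                   predicted_status = surface$predicted_status),
    file.path(out_dir, "surface.csv"), progress = FALSE)

  model_json <- list(
    stressor_models = list(
      table = stressors$table,
      models = purrr::map(stressors$models, model_as_list)
    ),
    environment_models = purrr::map(
      purrr::compact(env_models),
      function(pair) purrr::map(purrr::compact(pair),
                                function(ms) ms$table)),
    surface_model = model_as_list(surface_model),
    threshold = threshold
  )
  jsonlite::write_json(model_json, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  report <- list(
    seed = if (!is.null(study$config)) study$config$seed else NA,
    n_sites = nrow(study$site_environment),
    years = sort(unique(metrics$year)),
    config = if (!is.null(study$config)) unclass(study$config) else NULL,
    package_version = as.character(utils::packageVersion("reefstatus")),
    classification = as.list(table(classification$category)),
    best_stressor_model = stressors$table$label[1],
    threshold = threshold,
    comparisons = comparisons
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(c(
    sprintf("reefstatus %s | R %s", utils::packageVersion("reefstatus"),
            getRversion()),
    sprintf("run completed: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("seed: %s", report$seed),
    sprintf("sites: %d, years: %s", report$n_sites,
            paste(range(report$years), collapse = "-")),
    sprintf("best stressor model: %s", report$best_stressor_model)
  ), file.path(out_dir, "run_log.txt"))

  invisible(list(study = study, metrics = metrics, wq = wq,
                 site_table = site_table, status = status,
                 classification = classification, comparisons = comparisons,
                 ordination = ordination,
                 models = list(stressors = stressors, environment = env_models),
                 surface = surface, threshold = threshold))
}

model_as_list <- function(m) {
  list(
    label = m$label,
    terms = purrr::map(m$terms, function(t) list(vars = t$vars, exps = t$exps)),
    coefficients = m$coefficients,
    intercept = m$intercept,
    r_squared = m$r_squared,
    p_value = m$p_value,
    aic = m$aic,
    n = m$n
  )
}
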