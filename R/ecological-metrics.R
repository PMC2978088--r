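# Ecological status metrics computed from raw monitoring records:
# point-intercept cover, benthic substrate ratio, colony geometry, coral
# species richness per quadrat, Margalef's d, herbivorous fish biomass and
# macroinvertebrate density.

#' Estimate benthic cover from point-intercept records
#'
#' Converts annotated video-frame dots (point-intercept records) into
#' per-transect cover fractions. Each transect's dots are treated as a
#' multinomial sample over the controlled category vocabulary
#' ([benthic_categories()]); the site-year estimate is the mean of its
#' transect estimates (see [site_year_cover()]).
#'
#' @param points A data frame of benthic point records with columns
#'   `site_id`, `year`, `transect`, `category` (and optionally `genus` for
#'   coral dots).
#' @return A tibble of class `reef_cover` with one row per
#'   site-year-transect-category: columns `site_id`, `year`, `transect`,
#'   `category`, `cover` (fraction in \[0, 1\]) and `n_points` (dots on that
#'   transect). Every category appears for every transect (zero cover where
#'   absent), so fractions sum to 1 within a transect.
#' @examples
#' pts <- tibble::tibble(site_id = "S01", year = 2005, transect = 1,
#'                       category = rep(c("coral", "turf"), each = 150))
#' estimate_cover(pts)
#' @export
estimate_cover <- function(points) {
  check_columns(points, c("site_id", "year", "transect", "category"),
                "benthic point table")
  if (nrow(points) == 0) abort("no benthic points: every transect needs >= 1 point")
  bad <- setdiff(unique(points$category), benthic_categories())
  if (length(bad) > 0) {
    abort(sprintf("unknown benthic categor%s: %s (admissible: %s)",
                  if (length(bad) > 1) "ies" else "y",
                  paste(bad, collapse = ", "),
                  paste(benthic_categories(), collapse = ", ")))
  }
  out <- points |>
    dplyr::count(.data$site_id, .data$year, .data$transect, .data$category,
                 name = "n") |>
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("site_id"), !!rlang::sym("year"),
                     !!rlang::sym("transect")),
      category = benthic_categories(),
      fill = list(n = 0L)
    ) |>
    dplyr::group_by(.data$site_id, .data$year, .data$transect) |>
    dplyr::mutate(n_points = sum(.data$n), cover = .data$n / .data$n_points) |>
    dplyr::ungroup() |>
    dplyr::select("site_id", "year", "transect", "category", "cover", "n_points")
  class(out) <- c("reef_cover", class(out))
  out
}

#' Average transect cover up to the site-year level
#'
#' @param cover A `reef_cover` tibble from [estimate_cover()].
#' @return A tibble with one row per site-year-category; `cover` is the mean
#'   of the transect fractions and `n_transects` counts the replicates.
#' @export
site_year_cover <- function(cover) {
  check_columns(cover, c("site_id", "year", "transect", "category", "cover"),
                "cover table")
  cover |>
    dplyr::summarise(
      cover = mean(.data$cover),
      n_transects = dplyr::n(),
      .by = c("site_id", "year", "category")
    )
}

#' Benthic substrate ratio
#'
#' The ratio of substrate favourable to coral recruitment to substrate that
#' inhibits it: cover of coral + soft coral + (non-inhibitive) coralline
#' algae, divided by cover of macroalgae + turf algae + inhibitive coralline
#' algae. Sand and other invertebrates enter neither side. A zero
#' denominator yields `NA` (undefined sentinel) with a warning; downstream
#' statistics drop such rows rather than imputing a value.
#'
#' @param cover A long cover table with a `category` column, a `cover`
#'   column, and any grouping columns (e.g. `site_id`, `year`, `transect`).
#' @return A tibble with one row per group and a `substrate_ratio` column.
#' @examples
#' cov <- tibble::tibble(category = c("coral", "coralline", "macroalgae",
#'                                    "turf", "inhibitive_coralline"),
#'                       cover = c(0.40, 0.20, 0.10, 0.15, 0.05))
#' substrate_ratio(cov)  # 60/30 = 2
#' @export
substrate_ratio <- function(cover) {
  check_columns(cover, c("category", "cover"), "cover table")
  keys <- setdiff(names(cover), c("category", "cover", "n", "n_points",
                                  "n_transects"))
  out <- cover |>
    dplyr::summarise(
      favourable = sum(.data$cover[.data$category %in% ratio_numerator_categories()]),
      inhibitive = sum(.data$cover[.data$category %in% ratio_denominator_categories()]),
      .by = dplyr::all_of(keys)
    ) |>
    dplyr::mutate(substrate_ratio = dplyr::if_else(
      .data$inhibitive > 0, .data$favourable / .data$inhibitive, NA_real_
    ))
  if (anyNA(out$substrate_ratio)) {
    warn(sprintf(
      "substrate_ratio undefined (zero macroalgae+turf+inhibitive cover) for %d group(s); returned NA",
      sum(is.na(out$substrate_ratio))
    ))
  }
  out
}

#' Geometric diameter and planar area of a coral colony
#'
#' Colonies are measured by their maximum diameter and the diameter
#' perpendicular to it, and treated as circular. The geometric diameter is
#' the geometric mean `sqrt(d_max * d_perp)`; planar area is the circle of
#' that diameter.
#'
#' @param d_max,d_perp Numeric vectors of colony diameters (cm);
#'   `d_max >= d_perp > 0` elementwise.
#' @return A tibble with columns `diameter_cm` and `area_cm2`.
#' @examples
#' colony_geometry(16, 4)  # diameter 8 cm
#' @export
colony_geometry <- function(d_max, d_perp) {
  if (length(d_max) != length(d_perp)) abort("d_max and d_perp must have equal length")
  if (any(!is.finite(d_max)) || any(!is.finite(d_perp)) ||
      any(d_perp <= 0) || any(d_max <= 0)) {
    abort("colony diameters must be finite and positive")
  }
  if (any(d_max < d_perp)) {
    abort("inverted diameters: d_max must be >= d_perp for every colony")
  }
  diameter <- sqrt(d_max * d_perp)
  tibble::tibble(diameter_cm = diameter, area_cm2 = pi * (diameter / 2)^2)
}

#' Mean coral species richness per quadrat
#'
#' The average number of distinct coral species per 1 m^2 quadrat. The
#' quadrat census lists every surveyed quadrat, so quadrats in which no
#' colony was recorded contribute zero (the default; `include_empty = FALSE`
#' restricts the mean to occupied quadrats).
#'
#' @param colonies Colony records with columns `site_id`, `year`,
#'   `transect`, `quadrat`, `species`.
#' @param quadrats The quadrat census: one row per surveyed quadrat with
#'   columns `site_id`, `year`, `transect`, `quadrat`.
#' @param include_empty Count empty quadrats as richness zero? Default TRUE.
#' @return A tibble with one row per site-year and column
#'   `richness_per_quadrat`.
#' @export
richness_per_quadrat <- function(colonies, quadrats, include_empty = TRUE) {
  check_columns(colonies, c("site_id", "year", "transect", "quadrat", "species"),
                "colony table")
  check_columns(quadrats, c("site_id", "year", "transect", "quadrat"),
                "quadrat census")
  per_q <- quadrat_richness(colonies, quadrats)
  if (!include_empty) per_q <- dplyr::filter(per_q, .data$richness > 0)
  per_q |>
    dplyr::summarise(richness_per_quadrat = mean(.data$richness),
                     .by = c("site_id", "year"))
}

#' Species richness of each individual quadrat
#'
#' Replicate-level companion to [richness_per_quadrat()]; empty quadrats are
#' returned with richness 0. Colonies referencing a quadrat absent from the
#' census are an error.
#'
#' @inheritParams richness_per_quadrat
#' @return A tibble with one row per censused quadrat and a `richness`
#'   column.
#' @export
quadrat_richness <- function(colonies, quadrats) {
  key <- c("site_id", "year", "transect", "quadrat")
  census <- dplyr::distinct(quadrats, dplyr::across(dplyr::all_of(key)))
  orphans <- dplyr::anti_join(colonies, census, by = key)
  if (nrow(orphans) > 0) {
    ex <- orphans[1, key]
    abort(sprintf(
      "%d colony record(s) reference quadrats absent from the census (e.g. site %s year %s transect %s quadrat %s)",
      nrow(orphans), ex$site_id, ex$year, ex$transect, ex$quadrat))
  }
  counts <- colonies |>
    dplyr::summarise(richness = dplyr::n_distinct(.data$species),
                     .by = dplyr::all_of(key))
  census |>
    dplyr::left_join(counts, by = key) |>
    dplyr::mutate(richness = dplyr::coalesce(.data$richness, 0L))
}

#' Margalef's d
#'
#' Richness adjusted for abundance: `d = (S - 1) / ln(N)` where `S` is the
#' number of species with positive abundance and `N` the total number of
#' individuals. Undefined for `N <= 1`.
#'
#' @param abundances Numeric vector of per-species counts (zeros allowed).
#' @return The scalar d statistic.
#' @examples
#' margalef(rep(100, 10))  # 9 / ln(1000)
#' @export
margalef <- function(abundances) {
  if (any(abundances < 0) || any(!is.finite(abundances))) {
    abort("abundances must be finite and non-negative")
  }
  n_total <- sum(abundances)
  if (n_total <= 1) abort("Margalef's d is undefined for N <= 1 individuals")
  s <- sum(abundances > 0)
  (s - 1) / log(n_total)
}

#' Length-weight allometry
#'
#' Converts fish fork length to weight via `W = A * L^B` with
#' species-specific growth parameters.
#'
#' @param length_cm Fish length (cm), positive.
#' @param a,b Allometric parameters; `a > 0`.
#' @return Weight in grams, vectorised over inputs.
#' @export
fish_biomass <- function(length_cm, a, b) {
  if (any(length_cm <= 0) || any(!is.finite(length_cm))) {
    abort("fish length must be positive and finite")
  }
  if (any(a <= 0)) abort("allometric parameter A must be positive")
  a * length_cm^b
}

#' Herbivorous fish biomass per stationary point count
#'
#' Sums `count * A * L^B` over every herbivorous fish observed in each SPC
#' replicate. Herbivores are the scraper, excavator and detritivore trophic
#' groups; other trophic groups are ignored. A herbivore species missing
#' from the length-weight table is an error naming the species.
#'
#' @param fish SPC records with columns `site_id`, `year`, `replicate`,
#'   `species`, `trophic_group`, `length_cm`, `count`.
#' @param lw_params Length-weight parameter table with columns `species`,
#'   `A`, `B`.
#' @return A tibble with one row per site-year-replicate and column
#'   `biomass_g` (grams per SPC). Replicates present in `fish` but holding
#'   no herbivores get biomass 0.
#' @export
herbivore_biomass <- function(fish, lw_params) {
  check_columns(fish, c("site_id", "year", "replicate", "species",
                        "trophic_group", "length_cm", "count"), "fish SPC table")
  check_columns(lw_params, c("species", "A", "B"), "length-weight table")
  herb <- dplyr::filter(fish, .data$trophic_group %in% herbivore_trophic_groups())
  missing_sp <- setdiff(unique(herb$species), lw_params$species)
  if (length(missing_sp) > 0) {
    abort(sprintf("no length-weight parameters for species: %s",
                  paste(missing_sp, collapse = ", ")))
  }
  replicates <- dplyr::distinct(fish, .data$site_id, .data$year, .data$replicate)
  per_rep <- herb |>
    dplyr::inner_join(lw_params, by = "species") |>
    dplyr::mutate(w = .data$count * fish_biomass(.data$length_cm, .data$A, .data$B)) |>
    dplyr::summarise(biomass_g = sum(.data$w),
                     .by = c("site_id", "year", "replicate"))
  replicates |>
    dplyr::left_join(per_rep, by = c("site_id", "year", "replicate")) |>
    dplyr::mutate(biomass_g = dplyr::coalesce(.data$biomass_g, 0))
}

#' Macroinvertebrate density from belt transects
#'
#' Pools counts and surveyed area over transects within each site-year and
#' genus: density = total count / total area (individuals per m^2).
#'
#' @param inverts Belt-transect counts with columns `site_id`, `year`,
#'   `transect`, `genus`, `count`, `transect_area_m2`.
#' @return A tibble with one row per site-year-genus and column
#'   `density_m2`.
#' @export
invert_density <- function(inverts) {
  check_columns(inverts, c("site_id", "year", "genus", "count",
                           "transect_area_m2"), "invertebrate table")
  if (any(inverts$transect_area_m2 <= 0)) {
    abort("transect areas must be positive")
  }
  inverts |>
    dplyr::summarise(
      density_m2 = sum(.data$count) / sum(.data$transect_area_m2),
      .by = c("site_id", "year", "genus")
    )
}

#' Decompose a change in coral cover by genus
#'
#' Attributes the change in total coral cover between two surveys to
#' individual genera: each genus's delta and its share of the total change.
#' When the total change is a decline, shares over genera sum to 1 (a genus
#' that gained cover during a net decline gets a negative share).
#'
#' @param before,after Data frames with columns `genus` and `cover`
#'   (per-genus coral cover, same units in both) for the matched site or
#'   site set. Genus sets are aligned by union; a genus absent from one
#'   survey contributes zero cover there.
#' @return A tibble with columns `genus`, `cover_before`, `cover_after`,
#'   `delta` and `share`, plus attribute `total_delta`. If total change is
#'   exactly zero all shares are 0 and attribute `no_change` is TRUE.
#' @export
decompose_cover_change <- function(before, after) {
  check_columns(before, c("genus", "cover"), "'before' cover table")
  check_columns(after, c("genus", "cover"), "'after' cover table")
  merged <- dplyr::full_join(
    dplyr::summarise(before, cover_before = sum(.data$cover), .by = "genus"),
    dplyr::summarise(after, cover_after = sum(.data$cover), .by = "genus"),
    by = "genus"
  ) |>
    dplyr::mutate(
      cover_before = dplyr::coalesce(.data$cover_before, 0),
      cover_after = dplyr::coalesce(.data$cover_after, 0),
      delta = .data$cover_after - .data$cover_before
    )
  total <- sum(merged$delta)
  merged <- dplyr::mutate(
    merged,
    share = if (total == 0) 0 else .data$delta / total
  ) |>
    dplyr::arrange(.data$delta)
  attr(merged, "total_delta") <- total
  attr(merged, "no_change") <- total == 0
  merged
}

#' Assemble all site-year status metrics from a study's raw tables
#'
#' Runs every metric over the raw record tables and returns one row per
#' site-year: coral cover (%), benthic substrate ratio, coral species
#' richness per quadrat, Margalef's d over colony abundances, mean
#' herbivorous fish biomass per SPC (g), and urchin density (per m^2).
#' Replicate-level tables (transect cover and ratios, quadrat richness,
#' per-SPC biomass) are attached as attributes for downstream tests and
#' classification.
#'
#' @param study A `reef_study` list from [generate_study()] or
#'   [read_study()], or any list with elements `benthic_points`,
#'   `coral_colonies`, `quadrat_census`, `fish_spc`, `invert_transects`,
#'   `lw_params`.
#' @param urchin_genera Genera counted as grazing urchins; default
#'   Echinometra, Echinothrix, Diadema.
#' @return A `reef_metrics` tibble with columns `site_id`, `year`,
#'   `coral_cover`, `substrate_ratio`, `richness_per_quadrat`, `margalef_d`,
#'   `herbivore_biomass`, `urchin_density`; attributes `cover_transect`,
#'   `ratio_transect`, `richness_quadrat`, `biomass_replicate` hold the
#'   replicate-level values.
#' @export
site_year_metrics <- function(study,
                              urchin_genera = c("Echinometra", "Echinothrix",
                                                "Diadema")) {
  cover_t <- estimate_cover(study$benthic_points)
  cover_sy <- site_year_cover(cover_t)
  ratio_t <- suppressWarnings(substrate_ratio(cover_t))
  ratio_sy <- suppressWarnings(substrate_ratio(cover_sy))

  rich_q <- quadrat_richness(study$coral_colonies, study$quadrat_census)
  rich_sy <- rich_q |>
    dplyr::summarise(richness_per_quadrat = mean(.data$richness),
                     .by = c("site_id", "year"))

  marg_sy <- study$coral_colonies |>
    dplyr::count(.data$site_id, .data$year, .data$species) |>
    dplyr::summarise(
      margalef_d = if (sum(.data$n) > 1) margalef(.data$n) else NA_real_,
      .by = c("site_id", "year")
    )

  biomass_rep <- herbivore_biomass(study$fish_spc, study$lw_params)
  biomass_sy <- biomass_rep |>
    dplyr::summarise(herbivore_biomass = mean(.data$biomass_g),
                     .by = c("site_id", "year"))

  urchin_sy <- invert_density(study$invert_transects) |>
    dplyr::filter(.data$genus %in% urchin_genera) |>
    dplyr::summarise(urchin_density = sum(.data$density_m2),
                     .by = c("site_id", "year"))

  coral_sy <- cover_sy |>
    dplyr::filter(.data$category == "coral") |>
    dplyr::transmute(.data$site_id, .data$year, coral_cover = 100 * .data$cover)

  out <- coral_sy |>
    dplyr::left_join(dplyr::select(ratio_sy, "site_id", "year", "substrate_ratio"),
                     by = c("site_id", "year")) |>
    dplyr::left_join(rich_sy, by = c("site_id", "year")) |>
    dplyr::left_join(marg_sy, by = c("site_id", "year")) |>
    dplyr::left_join(biomass_sy, by = c("site_id", "year")) |>
    dplyr::left_join(urchin_sy, by = c("site_id", "year")) |>
    dplyr::mutate(urchin_density = dplyr::coalesce(.data$urchin_density, 0)) |>
    dplyr::arrange(.data$site_id, .data$year)
  attr(out, "cover_transect") <- cover_t
  attr(out, "ratio_transect") <- ratio_t
  attr(out, "richness_quadrat") <- rich_q
  attr(out, "biomass_replicate") <- biomass_rep
  class(out) <- c("reef_metrics", class(out))
  out
}
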