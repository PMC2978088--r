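# Seeded synthetic monitoring data emulating a high-island coral-reef
# program: 17 sites on 2-3 geological reef types, video point-intercept
# transects, point quadrats, stationary point counts, belt transects,
# watershed water-quality sampling, and a cyclone disturbance pulse whose
# recovery trajectories are driven by a latent water-quality x herbivory
# interaction.

# --- fixed taxon pools -------------------------------------------------------

coral_genera <- function() {
  c("Acropora", "Montipora", "Porites", "Pavona", "Pocillopora",
    "Stylophora", "Favia")
}

# 25-species coral pool; each species carries its genus.
coral_species_pool <- function() {
  tibble::tribble(
    ~species,                    ~genus,
    "Acropora hyacinthus",       "Acropora",
    "Acropora cytherea",         "Acropora",
    "Acropora muricata",         "Acropora",
    "Acropora nasuta",           "Acropora",
    "Acropora digitifera",       "Acropora",
    "Montipora grisea",          "Montipora",
    "Montipora capitata",        "Montipora",
    "Montipora patula",          "Montipora",
    "Montipora foveolata",       "Montipora",
    "Porites rus",               "Porites",
    "Porites lichen",            "Porites",
    "Porites lobata",            "Porites",
    "Porites cylindrica",        "Porites",
    "Pavona varians",            "Pavona",
    "Pavona chiriquiensis",      "Pavona",
    "Pocillopora damicornis",    "Pocillopora",
    "Pocillopora verrucosa",     "Pocillopora",
    "Pocillopora eydouxi",       "Pocillopora",
    "Stylophora pistillata",     "Stylophora",
    "Favia stelligera",          "Favia",
    "Favites halicora",          "Favia",
    "Goniastrea retiformis",     "Favia",
    "Leptastrea purpurea",       "Favia",
    "Astreopora myriophthalma",  "Favia",
    "Psammocora contigua",       "Favia"
  )
}

# Fish assemblage: surgeonfish/parrotfish herbivores plus bycatch taxa.
fish_species_table <- function() {
  tibble::tribble(
    ~species,                  ~trophic_group, ~base_count, ~mean_length,
    "Scarus psittacus",        "scraper",      3.5,         20,
    "Scarus globiceps",        "scraper",      2.5,         18,
    "Hipposcarus longiceps",   "scraper",      1.2,         30,
    "Chlorurus spilurus",      "excavator",    3.0,         22,
    "Chlorurus microrhinos",   "excavator",    0.8,         35,
    "Ctenochaetus striatus",   "detritivore",  7.0,         15,
    "Ctenochaetus binotatus",  "detritivore",  3.0,         13,
    "Acanthurus lineatus",     "grazer",       2.5,         18,
    "Naso lituratus",          "grazer",       1.5,         25,
    "Lutjanus fulvus",         "predator",     1.5,         25,
    "Caranx melampygus",       "predator",     0.5,         45,
    "Myripristis berndti",     "planktivore",  4.0,         18
  )
}

wq_constituents <- function() {
  tibble::tibble(
    constituent = c("bacteria", "NO2_NO3", "NH4", "PO4", "Total_P", "Total_N"),
    mu_log = log(c(100, 0.05, 0.03, 0.01, 0.02, 0.15))
  )
}

# --- configuration -----------------------------------------------------------

#' Scenario configuration for the synthetic monitoring program
#'
#' Defaults encode the emulated program: 17 sites across three geological
#' reef types, annual surveys 2003-2008, a cyclone pulse in 2004 removing a
#' site-specific 5-45% of coral cover, three 50 m video transects of 300
#' dots (60 frames x 5 dots), eight 1 m^2 quadrats per transect, five SPC
#' replicates, and six water-quality sampling events per watershed-year.
#' The latent recovery model is
#' `status_true = b1*zWQ + b2*zHerb + b3*zWQ*zHerb + Normal(0, noise_sd)`
#' with standardized stressor effects (`effect_wq`, `effect_herb`,
#' `effect_interaction`) defaulting to (0.5, 0.5, 1.0) and `noise_sd` 0.3;
#' post-disturbance trajectories of the substrate ratio and coral richness
#' have slopes proportional to `status_true`.
#'
#' @param n_sites Number of monitoring sites.
#' @param reef_type_fractions Proportions of sites in reef types 1/2/3
#'   (must sum to 1).
#' @param years Survey years.
#' @param effect_wq,effect_herb,effect_interaction Standardized effects of
#'   the latent stressors on the recovery slope.
#' @param noise_sd Residual SD of latent status.
#' @param disturbance_year Year of the cyclone pulse.
#' @param disturbance_loss_range Fractional coral-cover loss interval.
#' @param points_per_transect Dots per video transect.
#' @param transects_per_site Video transects per site.
#' @param quadrats_per_transect 1 m^2 quadrats tossed along each transect.
#' @param spc_replicates Stationary point counts per site.
#' @param wq_samples_per_year Water-quality sampling events per
#'   watershed-year.
#' @param fish_dispersion Negative-binomial size parameter k for SPC counts.
#' @param slope_scale Benthic-share shift per year per unit of latent
#'   status.
#' @param seed Root seed; every random draw descends from it through named
#'   substreams.
#' @return A validated list of class `reef_scenario`.
#' @export
scenario_config <- function(n_sites = 17,
                            reef_type_fractions = c(0.47, 0.41, 0.12),
                            years = 2003:2008,
                            effect_wq = 0.5,
                            effect_herb = 0.5,
                            effect_interaction = 1.0,
                            noise_sd = 0.3,
                            disturbance_year = 2004,
                            disturbance_loss_range = c(0.05, 0.45),
                            points_per_transect = 300,
                            transects_per_site = 3,
                            quadrats_per_transect = 8,
                            spc_replicates = 5,
                            wq_samples_per_year = 6,
                            fish_dispersion = 2,
                            slope_scale = 0.06,
                            seed = 42L) {
  cfg <- list(
    n_sites = as.integer(n_sites),
    reef_type_fractions = reef_type_fractions,
    years = sort(as.integer(years)),
    effect_wq = effect_wq, effect_herb = effect_herb,
    effect_interaction = effect_interaction,
    noise_sd = noise_sd,
    disturbance_year = as.integer(disturbance_year),
    disturbance_loss_range = disturbance_loss_range,
    points_per_transect = as.integer(points_per_transect),
    transects_per_site = as.integer(transects_per_site),
    quadrats_per_transect = as.integer(quadrats_per_transect),
    spc_replicates = as.integer(spc_replicates),
    wq_samples_per_year = as.integer(wq_samples_per_year),
    fish_dispersion = fish_dispersion,
    slope_scale = slope_scale,
    seed = as.integer(seed)
  )
  validate_scenario(cfg)
  structure(cfg, class = "reef_scenario")
}

validate_scenario <- function(cfg) {
  if (length(cfg$years) == 0) abort("years must be a non-empty list of survey years")
  counts <- c(cfg$n_sites, cfg$points_per_transect, cfg$transects_per_site,
              cfg$quadrats_per_transect, cfg$spc_replicates,
              cfg$wq_samples_per_year)
  if (any(counts <= 0)) abort("all design counts must be positive")
  if (abs(sum(cfg$reef_type_fractions) - 1) > 1e-8) {
    abort("reef_type_fractions must sum to 1")
  }
  if (any(cfg$reef_type_fractions < 0)) abort("reef_type_fractions must be non-negative")
  r <- cfg$disturbance_loss_range
  if (length(r) != 2 || any(r < 0) || any(r > 1) || r[1] > r[2]) {
    abort("disturbance_loss_range must be an increasing interval within [0, 1]")
  }
  effs <- c(cfg$effect_wq, cfg$effect_herb, cfg$effect_interaction, cfg$noise_sd)
  if (any(!is.finite(effs)) || cfg$noise_sd < 0) {
    abort("effect sizes must be finite and noise_sd non-negative")
  }
  invisible(cfg)
}

#' Read a scenario configuration from YAML or JSON
#'
#' Any field omitted from the file keeps its [scenario_config()] default.
#'
#' @param path A `.yaml`/`.yml` or `.json` file of configuration fields.
#' @return A `reef_scenario` configuration.
#' @export
read_scenario_config <- function(path) {
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  do.call(scenario_config, fields)
}

# --- generation --------------------------------------------------------------

# Largest-remainder allocation of sites to reef types.
allocate_reef_types <- function(n_sites, fractions) {
  raw <- fractions * n_sites
  base <- floor(raw)
  rem <- n_sites - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(seq_along(fractions), times = base)
}

# True benthic category shares for one site at one year. The cyclone frees a
# fraction `loss` of coral cover into turf/sand/inhibitive coralline; in each
# subsequent year the composition relaxes back toward its pre-disturbance
# baseline at a per-year rate increasing in latent status (no relaxation at
# strongly negative status), while negative status additionally converts
# favourable cover to turf/macroalgae/inhibitive coralline at `slope_scale`
# per year per unit of status. Early post-disturbance trajectories of the
# substrate ratio therefore have slope increasing in status_true.
benthic_shares <- function(c0, loss, status_true, year, disturbance_year,
                           slope_scale) {
  shares <- c(coral = c0, soft_coral = 0.03, coralline = 0.10,
              inhibitive_coralline = 0.04, turf = 0.15, macroalgae = 0.05,
              other_invertebrates = 0.02)
  shares["sand"] <- max(1 - sum(shares), 0.02)
  base <- shares / sum(shares)
  shares <- base
  if (year >= disturbance_year) {
    freed <- shares[["coral"]] * loss
    shares[["coral"]] <- shares[["coral"]] - freed
    shares[["turf"]] <- shares[["turf"]] + 0.60 * freed
    shares[["sand"]] <- shares[["sand"]] + 0.25 * freed
    shares[["inhibitive_coralline"]] <- shares[["inhibitive_coralline"]] +
      0.15 * freed
    dt <- year - disturbance_year
    if (dt > 0) {
      rho <- clamp(0.20 + 0.28 * status_true, 0.02, 0.9)
      deg <- slope_scale * max(0, -status_true)
      unfav <- c("turf", "macroalgae", "inhibitive_coralline")
      fav <- c("coral", "coralline")
      grow <- 0.75 * slope_scale * max(0, status_true)
      for (i in seq_len(dt)) {
        shares <- shares + rho * (base - shares)
        if (deg > 0) {
          take <- min(deg, sum(shares[fav]) - 2 * 0.01)
          if (take > 0) {
            shares[fav] <- shares[fav] - take * shares[fav] / sum(shares[fav])
            shares[unfav] <- shares[unfav] + take * c(0.60, 0.15, 0.25)
          }
        }
        if (grow > 0) {
          # favourable substrate expands beyond baseline where status is high
          give <- min(grow, sum(shares[unfav]) - 0.07)
          if (give > 0) {
            shares[unfav] <- shares[unfav] - give * shares[unfav] / sum(shares[unfav])
            shares[fav] <- shares[fav] + give * c(0.7, 0.3)
          }
        }
      }
    }
  }
  shares <- pmax(shares, 0.003)
  # turf never vanishes from a reef: keep the unfavourable pool bounded away
  # from zero so the substrate ratio stays finite and well scaled
  unfav <- c("turf", "macroalgae", "inhibitive_coralline")
  if (sum(shares[unfav]) < 0.05) {
    shares[unfav] <- shares[unfav] * 0.05 / sum(shares[unfav])
  }
  shares / sum(shares)
}

# Coral genus mix for one site-year; the disturbance removes mostly
# Acropora/Montipora (90% of the absolute loss) and low status drifts
# dominance toward Porites/Pavona while high status favours
# Pocillopora/Stylophora/faviids.
genus_mix <- function(loss, status_true, year, disturbance_year) {
  mix <- c(Acropora = 0.42, Montipora = 0.30, Porites = 0.11, Pavona = 0.05,
           Pocillopora = 0.06, Stylophora = 0.03, Favia = 0.03)
  if (year >= disturbance_year) {
    am <- c("Acropora", "Montipora")
    loss_am <- min(0.9 * loss, sum(mix[am]) * 0.98)
    mix[am] <- mix[am] * (1 - loss_am / sum(mix[am]))
    rest <- setdiff(names(mix), am)
    loss_rest <- loss - loss_am
    mix[rest] <- mix[rest] * (1 - min(loss_rest / sum(mix[rest]), 0.98))
    dt <- year - disturbance_year
    if (dt > 0) {
      if (status_true < 0) {
        shift <- min(0.05 * (-status_true) * dt, sum(mix[am]) * 0.8)
        mix[am] <- mix[am] * (1 - shift / sum(mix[am]))
        mix[c("Porites", "Pavona")] <- mix[c("Porites", "Pavona")] + shift * c(0.6, 0.4)
      } else {
        shift <- min(0.03 * status_true * dt, sum(mix[c("Porites", "Pavona")]) * 0.5)
        mix[c("Porites", "Pavona")] <- mix[c("Porites", "Pavona")] *
          (1 - shift / sum(mix[c("Porites", "Pavona")]))
        mix[c("Pocillopora", "Stylophora", "Favia", "Acropora")] <-
          mix[c("Pocillopora", "Stylophora", "Favia", "Acropora")] +
          shift * c(0.3, 0.2, 0.2, 0.3)
      }
    }
  }
  mix / sum(mix)
}

#' Generate a complete synthetic monitoring study
#'
#' Draws a full multi-year dataset with the causal structure the pipeline
#' assumes: latent site-level water-quality and herbivory z-scores drive a
#' latent recovery status (linear with a product interaction), which sets
#' the post-disturbance slopes of the benthic substrate ratio and coral
#' richness; benthic dots are multinomial draws from true transect cover,
#' colony diameters are lognormal, SPC counts are negative-binomial with
#' herbivore abundance tracking the herbivory z-score, and water-quality
#' concentrations decrease in the water-quality z-score with lognormal
#' noise. All draws descend from `config$seed` through named substreams, so
#' the same config and seed give byte-identical tables.
#'
#' @param config A `reef_scenario` from [scenario_config()].
#' @return An object of class `reef_study`: a list of tibbles
#'   `site_environment`, `benthic_points`, `coral_colonies`,
#'   `quadrat_census`, `fish_spc`, `invert_transects`, `water_quality`,
#'   `lw_params`, plus `latent_truth` (true z-scores and status; emitted for
#'   testing only, never consumed by the pipeline) and the `config`.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "reef_scenario")) config <- do.call(scenario_config, config)
  validate_scenario(config)
  n <- config$n_sites
  years <- config$years
  seed <- config$seed
  site_ids <- sprintf("S%02d", seq_len(n))
  shed_ids <- sprintf("W%02d", seq_len(n))

  # latent stressors and status
  latent <- with_stream(seed, "latent", {
    z_wq <- rnorm(n)
    z_herb <- rnorm(n)
    eps <- rnorm(n, 0, config$noise_sd)
    tibble::tibble(
      site_id = site_ids, z_wq = z_wq, z_herb = z_herb,
      status_true = config$effect_wq * z_wq + config$effect_herb * z_herb +
        config$effect_interaction * z_wq * z_herb + eps
    )
  })

  # site environment: covariates consistent with the latent water quality
  env <- with_stream(seed, "site_environment", {
    reef_type <- allocate_reef_types(n, config$reef_type_fractions)
    shed_area <- rlnorm(n, log(400), 0.7)
    wave <- rlnorm(n, log(1.5) + 0.35 * (reef_type == 1), 0.25)
    tibble::tibble(
      site_id = site_ids,
      watershed_id = shed_ids,
      reef_type = as.integer(reef_type),
      shed_area_ha = round(shed_area, 1),
      disturbed_land_frac = round(
        plogis(stats::qlogis(0.25) - 0.9 * latent$z_wq + rnorm(n, 0, 0.4)), 4),
      wave_exposure = round(wave, 3),
      human_pop = as.integer(round(exp(5.5 - 0.6 * latent$z_wq + rnorm(n, 0, 0.5)))),
      pig_pop = as.integer(round(exp(3.0 - 0.4 * latent$z_wq + rnorm(n, 0, 0.5))))
    )
  })

  site_years <- tidyr::expand_grid(site = seq_len(n), year = years)
  genera <- coral_genera()
  ppt <- config$points_per_transect
  frames <- rep(seq_len(ceiling(ppt / 5)), each = 5, length.out = ppt)
  dots <- rep(1:5, length.out = ppt)

  # benthic stream: per-site baseline cover and cyclone loss, then the dots
  site_base <- NULL
  benthic <- with_stream(seed, "benthic", {
    zs <- function(x) (x - mean(x)) / max(sd(x), 1e-9)
    c0 <- clamp(0.45 - 0.04 * zs(log(env$shed_area_ha)) -
                  0.04 * zs(log(env$wave_exposure)) + rnorm(n, 0, 0.04),
                0.25, 0.62)
    loss <- runif(n, config$disturbance_loss_range[1],
                  config$disturbance_loss_range[2])
    site_base <- list(c0 = c0, loss = loss)
    purrr::pmap(site_years, function(site, year) {
      shares <- benthic_shares(site_base$c0[site], site_base$loss[site],
                               latent$status_true[site], year,
                               config$disturbance_year, config$slope_scale)
      gmix <- genus_mix(site_base$loss[site], latent$status_true[site], year,
                        config$disturbance_year)
      purrr::map(seq_len(config$transects_per_site), function(tr) {
        # transect-to-transect wobble around the site-year truth
        g <- rgamma(length(shares), shape = shares * 350)
        p <- g / sum(g)
        counts <- as.vector(rmultinom(1, ppt, p))
        category <- sample(rep(names(shares), counts))
        genus <- rep(NA_character_, ppt)
        is_coral <- category == "coral"
        if (any(is_coral)) {
          genus[is_coral] <- sample(genera, sum(is_coral), replace = TRUE,
                                    prob = gmix)
        }
        tibble::tibble(
          site_id = site_ids[site], year = year, transect = tr,
          frame = frames, dot = dots, category = category, genus = genus
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })

  # coral colonies in quadrats
  pool <- coral_species_pool()
  colonies <- with_stream(seed, "colonies", {
    base_w <- rgamma(nrow(pool), shape = 6)  # site-independent species jitter
    purrr::pmap(site_years, function(site, year) {
      st <- latent$status_true[site]
      dt_post <- max(0, year - config$disturbance_year)
      gmix <- genus_mix(site_base$loss[site], st, year, config$disturbance_year)
      w <- base_w * gmix[pool$genus] /
        as.vector(table(pool$genus)[pool$genus])
      s_eff <- clamp(round(15 + 3 * st * min(dt_post, 3)), 5, nrow(pool))
      keep <- order(w, decreasing = TRUE)[seq_len(s_eff)]
      w_keep <- w[keep] / sum(w[keep])
      shares <- benthic_shares(site_base$c0[site], site_base$loss[site], st,
                               year, config$disturbance_year, config$slope_scale)
      lambda <- 8 + 6 * shares[["coral"]]
      n_q <- config$transects_per_site * config$quadrats_per_transect
      n_col <- rpois(n_q, lambda)
      total <- sum(n_col)
      if (total == 0) return(NULL)
      sp_idx <- keep[sample.int(s_eff, total, replace = TRUE, prob = w_keep)]
      meanlog <- log(8) + 0.06 * st * min(dt_post, 4)
      d_max <- round(rlnorm(total, meanlog, 0.5), 1)
      d_perp <- round(d_max * runif(total, 0.55, 1), 1)
      d_perp <- pmax(pmin(d_perp, d_max), 0.5)
      d_max <- pmax(d_max, d_perp)
      qdf <- tidyr::expand_grid(transect = seq_len(config$transects_per_site),
                                quadrat = seq_len(config$quadrats_per_transect))
      tibble::tibble(
        site_id = site_ids[site], year = year,
        transect = rep(qdf$transect, n_col),
        quadrat = rep(qdf$quadrat, n_col),
        species = pool$species[sp_idx],
        d_max_cm = d_max, d_perp_cm = d_perp
      )
    }) |> purrr::list_rbind()
  })

  quadrat_census <- tidyr::expand_grid(
    site_id = site_ids, year = years,
    transect = seq_len(config$transects_per_site),
    quadrat = seq_len(config$quadrats_per_transect)
  )

  # fish stationary point counts
  fish_tab <- fish_species_table()
  herb_groups <- herbivore_trophic_groups()
  fish <- with_stream(seed, "fish", {
    grid <- tidyr::expand_grid(site = seq_len(n), year = years,
                               replicate = seq_len(config$spc_replicates),
                               sp = seq_len(nrow(fish_tab)))
    mu <- fish_tab$base_count[grid$sp] *
      exp(0.5 * latent$z_herb[grid$site] *
            (fish_tab$trophic_group[grid$sp] %in% herb_groups))
    count <- rnbinom(nrow(grid), size = config$fish_dispersion, mu = mu)
    # split each species count over three adjacent 5-cm length bins
    keep <- count > 0
    grid <- grid[keep, ]; count <- count[keep]
    ml <- fish_tab$mean_length[grid$sp]
    n1 <- stats::rbinom(length(count), count, 0.25)
    n2 <- stats::rbinom(length(count), count - n1, 0.5 / 0.75)
    n3 <- count - n1 - n2
    out <- tibble::tibble(
      site_id = rep(site_ids[grid$site], 3),
      year = rep(grid$year, 3),
      replicate = rep(grid$replicate, 3),
      species = rep(fish_tab$species[grid$sp], 3),
      trophic_group = rep(fish_tab$trophic_group[grid$sp], 3),
      length_cm = c(ml - 5, ml, ml + 5),
      count = c(n1, n2, n3)
    ) |>
      dplyr::filter(.data$count > 0) |>
      dplyr::arrange(.data$site_id, .data$year, .data$replicate,
                     .data$species, .data$length_cm)
    out
  })

  # macroinvertebrate belt transects (urchins deliberately scarce)
  invert_genera <- tibble::tibble(
    genus = c("Echinometra", "Diadema", "Holothuria", "Linckia", "Tridacna"),
    mean_count = c(0.4, 0.15, 5, 3, 1.2)
  )
  inverts <- with_stream(seed, "inverts", {
    grid <- tidyr::expand_grid(site = seq_len(n), year = years,
                               transect = seq_len(config$transects_per_site),
                               g = seq_len(nrow(invert_genera)))
    tibble::tibble(
      site_id = site_ids[grid$site], year = grid$year,
      transect = grid$transect,
      genus = invert_genera$genus[grid$g],
      count = rpois(nrow(grid), invert_genera$mean_count[grid$g]),
      transect_area_m2 = 200
    )
  })

  # watershed water-quality sampling
  cons <- wq_constituents()
  wq <- with_stream(seed, "water_quality", {
    grid <- tidyr::expand_grid(site = seq_len(n), year = years,
                               event = seq_len(config$wq_samples_per_year),
                               c = seq_len(nrow(cons)))
    month <- sample(1:12, nrow(grid), replace = TRUE)
    tibble::tibble(
      watershed_id = shed_ids[grid$site],
      date = sprintf("%d-%02d-15", grid$year, month),
      constituent = cons$constituent[grid$c],
      concentration = signif(exp(cons$mu_log[grid$c] -
                                   0.7 * latent$z_wq[grid$site] +
                                   rnorm(nrow(grid), 0, 0.35)), 6)
    )
  })

  lw <- with_stream(seed, "lw_params", {
    tibble::tibble(
      species = fish_tab$species,
      A = round(runif(nrow(fish_tab), 0.008, 0.030), 4),
      B = round(runif(nrow(fish_tab), 2.90, 3.10), 3)
    )
  })

  structure(
    list(
      site_environment = env,
      benthic_points = benthic,
      coral_colonies = colonies,
      quadrat_census = quadrat_census,
      fish_spc = fish,
      invert_transects = inverts,
      water_quality = wq,
      lw_params = lw,
      latent_truth = latent,
      config = config
    ),
    class = "reef_study"
  )
}

#' @export
print.reef_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic reef monitoring study: %d sites, years %d-%d (seed %d)\n",
    nrow(x$site_environment), min(x$config$years), max(x$config$years),
    x$config$seed))
  for (nm in c("benthic_points", "coral_colonies", "fish_spc",
               "invert_transects", "water_quality")) {
    cat(sprintf("  %-18s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
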