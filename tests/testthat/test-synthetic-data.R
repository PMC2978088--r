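# The seeded synthetic monitoring-data generator.

test_that("configuration is validated", {
  expect_error(scenario_config(n_sites = 0), "positive")
  expect_error(scenario_config(points_per_transect = -5), "positive")
  expect_error(scenario_config(years = integer(0)), "years")
  expect_error(scenario_config(reef_type_fractions = c(0.5, 0.4)), "sum to 1")
  expect_error(scenario_config(disturbance_loss_range = c(0.5, 0.1)),
               "interval")
  expect_error(scenario_config(disturbance_loss_range = c(-0.1, 0.4)),
               "interval")
  expect_error(scenario_config(effect_wq = Inf), "finite")
  expect_error(scenario_config(noise_sd = -1), "finite|non-negative")
})

test_that("identical seeds give identical tables, different seeds differ", {
  a <- generate_study(small_config(seed = 3))
  b <- generate_study(small_config(seed = 3))
  for (nm in c("site_environment", "benthic_points", "coral_colonies",
               "fish_spc", "invert_transects", "water_quality",
               "latent_truth")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  c <- generate_study(small_config(seed = 4))
  expect_false(identical(a$benthic_points$category,
                         c$benthic_points$category))
})

test_that("the survey design is honoured exactly", {
  cfg <- small_config(seed = 2)
  st <- generate_study(cfg)
  per_transect <- dplyr::count(st$benthic_points, .data$site_id, .data$year,
                               .data$transect)
  expect_true(all(per_transect$n == cfg$points_per_transect))
  expect_equal(nrow(per_transect), 6 * 5 * 3)
  expect_equal(nrow(st$site_environment), cfg$n_sites)
  expect_equal(sort(unique(st$fish_spc$replicate)),
               seq_len(cfg$spc_replicates))
  expect_equal(nrow(st$quadrat_census),
               6 * 5 * cfg$transects_per_site * cfg$quadrats_per_transect)
  # latent truth is emitted for testing, one row per site
  expect_equal(nrow(st$latent_truth), cfg$n_sites)
  # default design: 300 dots = 60 frames x 5 dots
  st300 <- generate_study(scenario_config(n_sites = 2,
                                          reef_type_fractions = c(1, 0, 0),
                                          years = 2003:2004, seed = 1))
  one <- dplyr::filter(st300$benthic_points, .data$site_id == "S01",
                       .data$year == 2003, .data$transect == 1)
  expect_equal(nrow(one), 300)
  expect_equal(max(one$frame), 60)
  expect_equal(sort(unique(one$dot)), 1:5)
})

test_that("null effects leave recovery slopes uncorrelated with latent WQ", {
  cfg <- scenario_config(n_sites = 40, reef_type_fractions = c(0.5, 0.5, 0),
                         effect_wq = 0, effect_herb = 0,
                         effect_interaction = 0, noise_sd = 1,
                         points_per_transect = 100, quadrats_per_transect = 4,
                         spc_replicates = 2, wq_samples_per_year = 2,
                         seed = 19)
  st <- generate_study(cfg)
  m <- site_year_metrics(st)
  post <- dplyr::filter(m, .data$year >= cfg$disturbance_year,
                        !is.na(.data$substrate_ratio))
  slopes <- post |>
    dplyr::summarise(slope = unname(coef(lm(substrate_ratio ~ year))[2]),
                     .by = "site_id") |>
    dplyr::arrange(.data$site_id)
  z <- st$latent_truth$z_wq[match(slopes$site_id, st$latent_truth$site_id)]
  r_obs <- abs(cor(z, slopes$slope))
  # permutation oracle for the null sampling band
  set.seed(101)
  r_perm <- replicate(999, abs(cor(sample(z), slopes$slope)))
  expect_lt(r_obs, quantile(r_perm, 0.975))
})

test_that("transect frequencies converge to true cover at 10^4 dots", {
  cfg <- scenario_config(n_sites = 3, reef_type_fractions = c(1, 0, 0),
                         years = 2003:2004, points_per_transect = 10000,
                         quadrats_per_transect = 1, spc_replicates = 2,
                         wq_samples_per_year = 2, seed = 8)
  st <- generate_study(cfg)
  cov <- site_year_cover(estimate_cover(st$benthic_points))
  # recompute the generator's true site-year shares
  lt <- st$latent_truth
  env <- st$site_environment
  base <- with(
    list(), {
      # reproduce the site-level baseline draws from the benthic stream
      reefstatus:::with_stream(cfg$seed, "benthic", {
        zs <- function(x) (x - mean(x)) / max(sd(x), 1e-9)
        c0 <- reefstatus:::clamp(
          0.45 - 0.04 * zs(log(env$shed_area_ha)) -
            0.04 * zs(log(env$wave_exposure)) + rnorm(3, 0, 0.04),
          0.25, 0.62)
        loss <- runif(3, 0.05, 0.45)
        list(c0 = c0, loss = loss)
      })
    })
  for (s in 1:3) for (yr in cfg$years) {
    truth <- reefstatus:::benthic_shares(base$c0[s], base$loss[s],
                                         lt$status_true[s], yr,
                                         cfg$disturbance_year,
                                         cfg$slope_scale)
    est <- cov[cov$site_id == sprintf("S%02d", s) & cov$year == yr, ]
    est_v <- est$cover[match(names(truth), est$category)]
    # SE combines multinomial sampling and the transect Dirichlet wobble,
    # averaged over 3 transects; 3 SE familywise over the 48 category
    # comparisons this loop makes
    se <- sqrt((truth * (1 - truth) / 10000 +
                  truth * (1 - truth) / 351) / 3)
    expect_true(all(abs(est_v - truth) <= pmax(3 * se, 0.005)))
  }
})

test_that("stronger interaction effects steepen recovery where zWQ*zHerb > 0", {
  # scaled-down seed count for runtime; effect direction only
  slope_gap <- vapply(1:25, function(seed) {
    mean_slope <- function(b3) {
      cfg <- scenario_config(n_sites = 8, reef_type_fractions = c(0.5, 0.5, 0),
                             effect_interaction = b3, noise_sd = 0.1,
                             points_per_transect = 60,
                             quadrats_per_transect = 2, spc_replicates = 2,
                             wq_samples_per_year = 2, years = 2003:2007,
                             seed = seed)
      st <- generate_study(cfg)
      lt <- st$latent_truth
      m <- site_year_metrics(st)
      post <- dplyr::filter(m, .data$year >= cfg$disturbance_year,
                            !is.na(.data$substrate_ratio))
      slopes <- post |>
        dplyr::summarise(slope = unname(coef(lm(substrate_ratio ~ year))[2]),
                         .by = "site_id")
      pos <- lt$site_id[lt$z_wq * lt$z_herb > 0]
      mean(slopes$slope[slopes$site_id %in% pos])
    }
    mean_slope(1.5) - mean_slope(0)
  }, numeric(1))
  expect_gt(mean(slope_gap), 0)
  expect_gt(mean(slope_gap > 0), 0.7)
})

test_that("write_study round-trips losslessly through read_study", {
  dir <- withr::local_tempdir()
  st <- generate_study(small_config(seed = 6))
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "site_environment.csv")))
  expect_equal(length(readLines(file.path(dir, "site_environment.csv"))),
               6 + 1)  # header + one row per site
  back <- read_study(dir)
  for (nm in c("site_environment", "benthic_points", "coral_colonies",
               "quadrat_census", "fish_spc", "invert_transects",
               "water_quality", "lw_params", "latent_truth")) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(st[[nm]]),
                 tolerance = 1e-12)
  }
  expect_equal(back$config$seed, st$config$seed)
  expect_equal(back$config$years, st$config$years)

  # degenerate: an empty fish table still writes a valid header-only file
  st$fish_spc <- st$fish_spc[0, ]
  dir2 <- withr::local_tempdir()
  write_study(st, dir2)
  expect_equal(length(readLines(file.path(dir2, "fish_spc.csv"))), 1)
  back2 <- read_study(dir2)
  expect_equal(nrow(back2$fish_spc), 0)
})

test_that("scenario configs round-trip through YAML and JSON", {
  cfg <- small_config(seed = 12)
  y <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), y)
  expect_equal(read_scenario_config(y), cfg)
  j <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), j, auto_unbox = TRUE, digits = NA)
  expect_equal(read_scenario_config(j), cfg)
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(not_a_field = 1), bad)
  expect_error(read_scenario_config(bad), "unknown configuration field")
})
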