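# Site-year ecological metrics computed from raw monitoring records.

test_that("estimate_cover turns dots into multinomial proportions", {
  pure <- estimate_cover(make_points(c(coral = 300)))
  expect_equal(pure$cover[pure$category == "coral"], 1)
  expect_equal(sum(pure$cover), 1)

  half <- estimate_cover(make_points(c(coral = 150, turf = 150)))
  expect_equal(half$cover[half$category == "coral"], 0.5)
  expect_equal(half$cover[half$category == "turf"], 0.5)
  expect_equal(half$n_points, rep(300L, 8))

  expect_error(estimate_cover(make_points(c(`lava rock` = 10))),
               "unknown benthic category")
  expect_error(estimate_cover(make_points(c(coral = 0))), "point")
})

test_that("per-transect cover fractions always sum to one", {
  set.seed(41)
  for (i in 1:20) {
    counts <- rmultinom(1, sample(50:400, 1), runif(8))[, 1]
    names(counts) <- benthic_categories()
    cov <- estimate_cover(make_points(counts[counts > 0]))
    expect_equal(sum(cov$cover), 1, tolerance = 1e-9)
    expect_true(all(cov$cover >= 0 & cov$cover <= 1))
  }
})

test_that("site-year cover is the mean of transect estimates", {
  pts <- dplyr::bind_rows(
    make_points(c(coral = 100), transect = 1),
    make_points(c(coral = 50, turf = 50), transect = 2)
  )
  sy <- site_year_cover(estimate_cover(pts))
  expect_equal(sy$cover[sy$category == "coral"], 0.75)
  expect_equal(sy$n_transects[1], 2L)
})

test_that("substrate ratio follows the favourable/inhibitive definition", {
  expect_equal(
    substrate_ratio(make_cover(c(coral = 0.15, soft_coral = 0.10,
                                 coralline = 0.05, macroalgae = 0.10,
                                 turf = 0.15, inhibitive_coralline = 0.05))
    )$substrate_ratio, 1)
  expect_equal(
    substrate_ratio(make_cover(c(coral = 0.40, soft_coral = 0,
                                 coralline = 0.20, macroalgae = 0.10,
                                 turf = 0.15, inhibitive_coralline = 0.05))
    )$substrate_ratio, 2)
  # sand and other invertebrates enter neither side
  with_sand <- substrate_ratio(make_cover(c(coral = 0.3, turf = 0.3,
                                            sand = 0.4)))
  expect_equal(with_sand$substrate_ratio, 1)
  expect_warning(
    out <- substrate_ratio(make_cover(c(coral = 0.5, sand = 0.5))),
    "undefined")
  expect_true(is.na(out$substrate_ratio))
})

test_that("colony geometry assumes circular colonies", {
  g <- colony_geometry(10, 10)
  expect_equal(g$diameter_cm, 10)
  expect_equal(g$area_cm2, 25 * pi)
  expect_equal(colony_geometry(16, 4)$diameter_cm, 8)
  expect_error(colony_geometry(4, 16), "inverted")
  expect_error(colony_geometry(0, 0), "positive")
  expect_error(colony_geometry(5, -1), "positive")
})

test_that("richness per quadrat averages distinct species, empties included", {
  no_colonies <- make_colonies(list("x"))[0, ]
  expect_equal(
    richness_per_quadrat(no_colonies, make_census(4))$richness_per_quadrat, 0)
  spp <- lapply(c(3, 5, 4, 4, 4, 4, 4, 4), function(k) paste0("sp", 1:k))
  expect_equal(
    richness_per_quadrat(make_colonies(spp), make_census(8))$richness_per_quadrat,
    4)
  expect_equal(
    richness_per_quadrat(make_colonies(list("Porites rus")),
                         make_census(1))$richness_per_quadrat, 1)
  # empty quadrats drive the mean down unless excluded
  half_empty <- make_colonies(list(c("a", "b"), character(0)))
  expect_equal(
    richness_per_quadrat(half_empty, make_census(2))$richness_per_quadrat, 1)
  expect_equal(
    richness_per_quadrat(half_empty, make_census(2),
                         include_empty = FALSE)$richness_per_quadrat, 2)
  orphan <- make_colonies(list("a", "b"))
  expect_error(richness_per_quadrat(orphan, make_census(1)), "census")
})

test_that("Margalef's d is (S-1)/ln(N)", {
  expect_equal(margalef(c(2, 0, 0)), 0)          # one species, any N >= 2
  expect_equal(margalef(rep(100, 10)), 9 / log(1000))
  expect_equal(margalef(rep(100, 10)), 1.302883445709755, tolerance = 1e-12)
  expect_error(margalef(c(1)), "undefined")
  expect_error(margalef(c(-1, 3)), "non-negative")
  # monotone in S at fixed N
  d_few <- margalef(c(50, 50))
  d_many <- margalef(rep(10, 10))
  expect_lt(d_few, d_many)
})

test_that("length-weight allometry W = A L^B", {
  expect_equal(fish_biomass(7, 1, 1), 7)
  # frozen high-precision evaluation of 0.0121 * 20^3.05
  expect_equal(fish_biomass(20, 0.0121, 3.05), 112.4415586453013,
               tolerance = 1e-12)
  expect_error(fish_biomass(0, 1, 3), "positive")
  expect_error(fish_biomass(10, 0, 3), "positive")
  l <- seq(5, 40, by = 5)
  expect_true(all(diff(fish_biomass(l, 0.02, 3.0)) > 0))
})

test_that("herbivore biomass sums scrapers, excavators and detritivores", {
  fish <- tibble::tibble(
    site_id = "S01", year = 2007, replicate = c(1L, 1L, 1L, 2L),
    species = c("scarus", "cteno", "jack", "jack"),
    trophic_group = c("scraper", "detritivore", "predator", "predator"),
    length_cm = c(20, 15, 30, 30), count = c(2L, 3L, 1L, 2L)
  )
  lw <- tibble::tibble(species = c("scarus", "cteno"), A = c(0.02, 0.03),
                       B = c(3, 2.9))
  out <- herbivore_biomass(fish, lw)
  expect_equal(nrow(out), 2)
  expect_equal(out$biomass_g[out$replicate == 1],
               2 * 0.02 * 20^3 + 3 * 0.03 * 15^2.9)
  expect_equal(out$biomass_g[out$replicate == 2], 0)  # predators only
  # missing parameters for a herbivore are an error naming the species
  fish$trophic_group[3] <- "excavator"
  expect_error(herbivore_biomass(fish, lw), "jack")
})

test_that("invertebrate density pools counts over pooled area", {
  inv <- tibble::tibble(site_id = "S01", year = 2005, transect = 1:3,
                        genus = "Echinometra", count = c(1L, 0L, 2L),
                        transect_area_m2 = 200)
  expect_equal(invert_density(inv)$density_m2, 3 / 600)
  inv$count <- 0L
  expect_equal(invert_density(inv)$density_m2, 0)
  inv$transect_area_m2 <- 0
  expect_error(invert_density(inv), "positive")
})

test_that("cover-change decomposition attributes the decline by genus", {
  before <- tibble::tibble(genus = c("Acropora", "Montipora", "Porites"),
                           cover = c(20, 12, 8))
  after <- tibble::tibble(genus = c("Acropora", "Montipora", "Porites"),
                          cover = c(8, 6, 6))
  dec <- decompose_cover_change(before, after)
  am <- sum(dec$share[dec$genus %in% c("Acropora", "Montipora")])
  expect_equal(am, 0.90)
  expect_equal(sum(dec$share), 1)
  expect_equal(attr(dec, "total_delta"), -20)

  same <- decompose_cover_change(before, before)
  expect_true(all(same$share == 0))
  expect_true(attr(same, "no_change"))

  # a genus gaining cover during a net decline takes a negative share
  after2 <- tibble::tibble(genus = c("Acropora", "Montipora", "Porites"),
                           cover = c(5, 6, 10))
  dec2 <- decompose_cover_change(before, after2)
  expect_lt(dec2$share[dec2$genus == "Porites"], 0)
  expect_equal(sum(dec2$share), 1)
})

test_that("site_year_metrics assembles every metric with replicate tables", {
  st <- generate_study(small_config(seed = 5))
  m <- site_year_metrics(st)
  expect_setequal(
    names(m),
    c("site_id", "year", "coral_cover", "substrate_ratio",
      "richness_per_quadrat", "margalef_d", "herbivore_biomass",
      "urchin_density"))
  expect_equal(nrow(m), 6 * 5)
  expect_true(all(m$coral_cover >= 0 & m$coral_cover <= 100))
  expect_true(all(m$margalef_d >= 0, na.rm = TRUE))
  expect_true(all(m$substrate_ratio >= 0, na.rm = TRUE))
  for (a in c("cover_transect", "ratio_transect", "richness_quadrat",
              "biomass_replicate")) {
    expect_s3_class(attr(m, a), "data.frame")
  }
  expect_equal(nrow(attr(m, "richness_quadrat")), 6 * 5 * 3 * 3)
})
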