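# Shared fixture builders for the unit suite.

# Benthic point records with the given per-category dot counts on one transect.
make_points <- function(counts, site = "S01", year = 2005, transect = 1) {
  tibble::tibble(
    site_id = site, year = year, transect = transect,
    category = rep(names(counts), counts)
  )
}

# A long cover table from named fractions (single group).
make_cover <- function(fracs) {
  tibble::tibble(category = names(fracs), cover = unname(fracs))
}

# Colony records in a single site-year; `species_by_quadrat` is a list of
# character vectors, one element per quadrat (transect 1).
make_colonies <- function(species_by_quadrat, site = "S01", year = 2005) {
  purrr::imap(species_by_quadrat, function(spp, q) {
    if (length(spp) == 0) return(NULL)
    tibble::tibble(site_id = site, year = year, transect = 1L,
                   quadrat = as.integer(q), species = spp,
                   d_max_cm = 10, d_perp_cm = 8)
  }) |> purrr::list_rbind()
}

make_census <- function(n_quadrats, site = "S01", year = 2005) {
  tibble::tibble(site_id = site, year = year, transect = 1L,
                 quadrat = seq_len(n_quadrats))
}

# A fast scenario for tests that only need structure, not statistical power.
small_config <- function(seed = 1, ...) {
  scenario_config(n_sites = 6, reef_type_fractions = c(0.5, 0.5, 0),
                  years = 2003:2007, points_per_transect = 60,
                  quadrats_per_transect = 3, spc_replicates = 3,
                  wq_samples_per_year = 3, seed = seed, ...)
}

# Water-quality samples from a watershed x constituent concentration matrix.
make_wq <- function(mat) {
  tibble::tibble(
    watershed_id = rep(rownames(mat), ncol(mat)),
    constituent = rep(colnames(mat), each = nrow(mat)),
    concentration = as.vector(mat)
  )
}
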