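# Internal helpers shared across modules.

#' Benthic category vocabulary
#'
#' The controlled vocabulary for point-intercept benthic records: hard coral
#' (genus carried in a separate column), soft coral, non-inhibitive coralline
#' algae, coralline algae known to overgrow coral ("inhibitive"), turf algae
#' (< 2 cm), macroalgae (> 2 cm), sand, and other invertebrates. Records with
#' any other category are rejected by [estimate_cover()].
#'
#' @return Character vector of the eight admissible category codes.
#' @export
benthic_categories <- function() {
  c("coral", "soft_coral", "coralline", "inhibitive_coralline",
    "turf", "macroalgae", "sand", "other_invertebrates")
}

# Categories entering the numerator / denominator of the substrate ratio.
ratio_numerator_categories   <- function() c("coral", "soft_coral", "coralline")
ratio_denominator_categories <- function() c("macroalgae", "turf", "inhibitive_coralline")

# Trophic groups counted as herbivores in biomass estimates.
herbivore_trophic_groups <- function() c("scraper", "excavator", "detritivore")

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Significance star codes used on group-comparison figures.
star_code <- function(p) {
  dplyr::case_when(
    is.na(p)  ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01  ~ "**",
    p < 0.05  ~ "*",
    TRUE      ~ ""
  )
}

# Sample skewness and excess kurtosis (moment estimators).
moment_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

moment_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

# --- seeded substreams -------------------------------------------------------
#
# All randomness in the synthetic-data module flows from one root seed. Each
# named component draws from its own substream whose seed is derived as
#   substream_seed = (root_seed + 1000003 * index(component)) mod (2^31 - 2) + 1
# with a fixed component index table, so adding draws to one component never
# perturbs another. The global RNG state is saved and restored around every
# substream so the generator does not disturb the caller's RNG.

stream_index <- function(id) {
  ids <- c(site_environment = 1L, latent = 2L, benthic = 3L, colonies = 4L,
           fish = 5L, inverts = 6L, water_quality = 7L, lw_params = 8L,
           pipeline = 9L)
  idx <- ids[[id]]
  if (is.null(idx)) abort(sprintf("unknown RNG stream id '%s'", id))
  idx
}

substream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) + 1000003 * stream_index(id)) %%
               (.Machine$integer.max - 1)) + 1L
}

with_stream <- function(seed, id, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, id))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
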