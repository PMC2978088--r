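# Water-quality index, within-reef-type standardization, and the
# replicate-crossed water-quality x herbivory interaction term.

#' Rank-based water-quality index
#'
#' Builds a per-watershed index from repeated constituent samples (bacteria
#' and nutrient concentrations). Within each constituent every sample is
#' ranked across all watersheds (ties get average ranks); watersheds are
#' then ordered by their mean sample rank and assigned an across-watershed
#' rank from 1 to the number of watersheds, oriented so that LOWER
#' concentration earns a HIGHER rank (higher index = cleaner water, since
#' concentrations are "bads"; set `direction` per constituent for any
#' "goods"). The index is the mean of a watershed's constituent ranks;
#' constituents never measured in a watershed are skipped in that
#' watershed's mean. Because only ranks enter, the index is invariant under
#' any strictly increasing transform of the concentrations.
#'
#' @param samples Water-quality samples with columns `watershed_id`,
#'   `constituent`, `concentration` (a `date` column may be present and is
#'   ignored).
#' @param direction Either a single string or a named character vector per
#'   constituent; `"lower_better"` (default) ranks low concentrations high,
#'   `"higher_better"` the reverse.
#' @return A tibble of class `reef_wq_index` with columns `watershed_id` and
#'   `index`, carrying the per-constituent watershed ranks in attribute
#'   `ranks` (long tibble: watershed_id, constituent, rank).
#' @examples
#' s <- tibble::tibble(watershed_id = rep(c("A", "B", "C"), 2),
#'                     constituent = rep(c("NO2_NO3", "Total_N"), each = 3),
#'                     concentration = c(1, 2, 3, 1, 2, 3))
#' wq_index(s)  # A (cleanest) gets index 3
#' @export
wq_index <- function(samples, direction = "lower_better") {
  check_columns(samples, c("watershed_id", "constituent", "concentration"),
                "water-quality table")
  samples <- dplyr::filter(samples, !is.na(.data$concentration))
  n_sheds <- dplyr::n_distinct(samples$watershed_id)
  if (n_sheds < 2) abort("wq_index needs samples from >= 2 watersheds")

  constituents <- unique(samples$constituent)
  dir_for <- function(con) {
    d <- if (length(direction) == 1 && is.null(names(direction))) direction
         else direction[[con]] %||% "lower_better"
    match.arg(d, c("lower_better", "higher_better"))
  }

  # drop constituents observed in a single watershed (rank is meaningless)
  coverage <- samples |>
    dplyr::summarise(n_sheds = dplyr::n_distinct(.data$watershed_id),
                     .by = "constituent")
  narrow <- coverage$constituent[coverage$n_sheds < 2]
  if (length(narrow) > 0) {
    warn(sprintf("constituent(s) measured in < 2 watersheds dropped from index: %s",
                 paste(narrow, collapse = ", ")))
    samples <- dplyr::filter(samples, !(.data$constituent %in% narrow))
  }
  if (nrow(samples) == 0) abort("no rankable constituents remain")

  ranks <- samples |>
    dplyr::mutate(
      sample_rank = rank(.data$concentration, ties.method = "average"),
      .by = "constituent") |>
    dplyr::summarise(mean_sample_rank = mean(.data$sample_rank),
                     .by = c("constituent", "watershed_id")) |>
    dplyr::mutate(rank = if (dir_for(.data$constituent[1]) == "lower_better") {
      rank(-.data$mean_sample_rank, ties.method = "average")
    } else {
      rank(.data$mean_sample_rank, ties.method = "average")
    }, .by = "constituent") |>
    dplyr::select("watershed_id", "constituent", "rank")

  empty <- setdiff(unique(samples$watershed_id), unique(ranks$watershed_id))
  if (length(empty) > 0) {
    abort(sprintf("watershed(s) with no constituent measurements: %s",
                  paste(empty, collapse = ", ")))
  }

  out <- ranks |>
    dplyr::summarise(index = mean(.data$rank), .by = "watershed_id") |>
    dplyr::arrange(.data$watershed_id)
  attr(out, "ranks") <- ranks
  class(out) <- c("reef_wq_index", class(out))
  out
}

#' Standardize values within geological reef types
#'
#' Z-scores a variable within groups (reef types), giving each geological
#' setting equal weighting: within each group, `(x - mean) / sd` using the
#' sample SD (n - 1 denominator). Groups with a single member or zero
#' within-group spread are an error naming the group.
#'
#' @param data A data frame.
#' @param value Column to standardize (tidy-eval).
#' @param group Grouping column, e.g. reef type (tidy-eval).
#' @param name Name of the output z-score column (default `"z"`).
#' @return `data` with the z-score column appended.
#' @examples
#' d <- tibble::tibble(reef_type = 1, x = c(1, 2, 3))
#' standardize(d, x, reef_type)$z  # -1 0 1
#' @export
standardize <- function(data, value, group, name = "z") {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  vals <- rlang::eval_tidy(value, data)
  grps <- rlang::eval_tidy(group, data)
  if (anyNA(vals)) abort("standardize: values contain NA; drop or impute first")
  z <- rep(NA_real_, length(vals))
  for (g in unique(grps)) {
    i <- which(grps == g)
    if (length(i) < 2) {
      abort(sprintf("standardize: group '%s' has a single member; z-score undefined", g))
    }
    s <- sd(vals[i])
    if (s == 0) {
      abort(sprintf("standardize: group '%s' has zero within-group SD", g))
    }
    z[i] <- (vals[i] - mean(vals[i])) / s
  }
  data[[name]] <- z
  data
}

#' Replicate-crossed interaction term
#'
#' Constructs the water-quality-by-herbivory interaction variable by pairing
#' every replicate herbivory estimate with every water-quality measure: the
#' exhaustive cross-product of the two standardized replicate sets (random
#' pairing iterated over all combinations is order-free once exhaustive).
#' Returns the full product sample with its mean, variance and normality
#' diagnostics, so the caller can check the interaction variable is
#' acceptably normal before using its mean and variance.
#'
#' @param herb_replicates,wq_replicates Numeric vectors of standardized
#'   (z-scored) replicate values; each needs >= 2 replicates.
#' @return An object of class `reef_interaction`: a list with elements
#'   `sample` (length `n_h * n_w`), `mean`, `variance`, `skewness`,
#'   `kurtosis` (excess), `shapiro_p` (NA when the sample is too small or
#'   constant), `n_herb`, `n_wq`.
#' @examples
#' it <- interaction_term(c(-1, 1), c(-1, 1))
#' it$sample  # 1 -1 -1 1
#' @export
interaction_term <- function(herb_replicates, wq_replicates) {
  if (length(herb_replicates) < 2 || length(wq_replicates) < 2) {
    abort("interaction_term needs >= 2 replicates in each set")
  }
  if (anyNA(herb_replicates) || anyNA(wq_replicates)) {
    abort("replicate values must not contain NA")
  }
  products <- as.vector(outer(herb_replicates, wq_replicates))
  shp <- if (length(products) >= 3 && length(products) <= 5000 &&
             sd(products) > 0) {
    tryCatch(shapiro.test(products)$p.value, error = function(e) NA_real_)
  } else {
    NA_real_
  }
  structure(
    list(
      sample = products,
      mean = mean(products),
      variance = var(products),
      skewness = moment_skewness(products),
      kurtosis = moment_kurtosis(products),
      shapiro_p = shp,
      n_herb = length(herb_replicates),
      n_wq = length(wq_replicates)
    ),
    class = "reef_interaction"
  )
}

#' @export
print.reef_interaction <- function(x, ...) {
  cat(sprintf(
    "Replicate-crossed interaction sample: %d x %d = %d products\n  mean %.4f  variance %.4f  skewness %.3f  excess kurtosis %.3f  Shapiro p %s\n",
    x$n_herb, x$n_wq, length(x$sample), x$mean, x$variance, x$skewness,
    x$kurtosis, ifelse(is.na(x$shapiro_p), "NA", format(x$shapiro_p, digits = 3))
  ))
  invisible(x)
}
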