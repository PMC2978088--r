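# Recovery classification from temporal change in sensitive metrics, the
# continuous status score, and group comparison tests.

#' Classify a site's recovery from pre/post metric replicates
#'
#' A site is a "high-recovery" reef when mean coral species richness and the
#' benthic substrate ratio both remained statistically similar (or
#' significantly increased) after the disturbance, and a "low-recovery" reef
#' when both metrics significantly declined. Mixed outcomes are
#' "unclassified" and excluded from group tests. Change per metric is
#' assessed with a paired t-test on replicate-level values matched by
#' replicate index.
#'
#' @param pre,post Data frames of replicate-level metric values before and
#'   after the disturbance. Each must contain the columns named in
#'   `metrics`; rows are matched by position (or by a shared `replicate`
#'   column if both have one). At least 3 matched replicates per metric.
#'   The two metrics may have different replicate structures, in which case
#'   pass NA padding-free data via separate columns of equal length per
#'   metric using `metric_pairs` instead.
#' @param metrics Character vector of metric column names; default
#'   `c("richness", "substrate_ratio")`.
#' @param alpha Significance level, default 0.05.
#' @param metric_pairs Optional alternative input: a named list, one element
#'   per metric, each a list/data frame with elements `pre` and `post`
#'   (equal-length numeric vectors). Overrides `pre`/`post`.
#' @return An object of class `reef_classification`: list with `category`
#'   ("high", "low" or "unclassified"), `alpha`, and `tests` (tibble with
#'   one row per metric: statistic, df, p, mean_diff, direction).
#' @export
classify_recovery <- function(pre = NULL, post = NULL,
                              metrics = c("richness", "substrate_ratio"),
                              alpha = 0.05, metric_pairs = NULL) {
  if (is.null(metric_pairs)) {
    if (is.null(pre) || is.null(post)) {
      abort("supply pre and post replicate tables, or metric_pairs")
    }
    check_columns(pre, metrics, "'pre' table")
    check_columns(post, metrics, "'post' table")
    if ("replicate" %in% names(pre) && "replicate" %in% names(post)) {
      merged <- dplyr::inner_join(pre, post, by = "replicate",
                                  suffix = c("_pre", "_post"))
      metric_pairs <- lapply(setNames(metrics, metrics), function(m) {
        list(pre = merged[[paste0(m, "_pre")]],
             post = merged[[paste0(m, "_post")]])
      })
    } else {
      if (nrow(pre) != nrow(post)) {
        abort("pre and post must have equal replicate counts (matched by position)")
      }
      metric_pairs <- lapply(setNames(metrics, metrics), function(m) {
        list(pre = pre[[m]], post = post[[m]])
      })
    }
  }

  tests <- purrr::imap(metric_pairs, function(pair, m) {
    x <- pair$pre
    y <- pair$post
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3) {
      abort(sprintf("metric '%s': fewer than 3 matched pre/post replicates", m))
    }
    d <- y - x
    if (sd(d) == 0) {
      # constant difference: degenerate paired t
      p <- if (mean(d) == 0) 1 else 0
      stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      tibble::tibble(metric = m, statistic = stat, df = length(d) - 1,
                     p = p, mean_diff = mean(d),
                     direction = sign(mean(d)))
    } else {
      tt <- t.test(y, x, paired = TRUE)
      tibble::tibble(metric = m, statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p = tt$p.value,
                     mean_diff = unname(tt$estimate),
                     direction = sign(unname(tt$estimate)))
    }
  }) |>
    purrr::list_rbind()

  declined <- tests$p < alpha & tests$mean_diff < 0
  non_declining <- tests$p >= alpha | tests$mean_diff > 0
  category <- if (all(declined)) "low"
              else if (all(non_declining)) "high"
              else "unclassified"
  structure(list(category = category, alpha = alpha, tests = tests),
            class = "reef_classification")
}

#' @export
print.reef_classification <- function(x, ...) {
  cat(sprintf("Recovery classification: %s (alpha = %g)\n", x$category, x$alpha))
  print(x$tests)
  invisible(x)
}

#' Continuous recovery status score
#'
#' The continuous dependent variable for island-wide regression: the sum of
#' the within-reef-type z-scores of coral species richness and the benthic
#' substrate ratio. Within every reef type the scores average zero, so
#' status expresses standing relative to sites in the same geological
#' setting.
#'
#' @param metrics Site-level metric table with columns `site_id`,
#'   `richness`, `substrate_ratio` and the reef-type column.
#' @param reef_type Reef-type grouping column (tidy-eval), default
#'   `reef_type`.
#' @return A tibble with `site_id`, the reef-type column, `z_richness`,
#'   `z_ratio` and `status = z_richness + z_ratio`.
#' @export
status_score <- function(metrics, reef_type = reef_type) {
  reef_type <- rlang::enquo(reef_type)
  check_columns(metrics, c("site_id", "richness", "substrate_ratio"),
                "site metric table")
  out <- metrics |>
    standardize(.data$richness, !!reef_type, name = "z_richness") |>
    standardize(.data$substrate_ratio, !!reef_type, name = "z_ratio") |>
    dplyr::mutate(status = .data$z_richness + .data$z_ratio)
  tibble::as_tibble(out)
}

#' Compare a stressor between high- and low-recovery reefs
#'
#' Two-sample test on replicate-level values of the water-quality index,
#' herbivore biomass, or the interaction term between recovery categories.
#' The default is Welch's unequal-variance t-test on the pooled replicate
#' values; `method = "paired"` pairs the vectors elementwise (they must
#' then be of equal length, e.g. matched by survey year). P-values get the
#' conventional star codes (*p<0.05, **p<0.01, ***p<0.001).
#'
#' @param high,low Numeric replicate-level values for the two categories;
#'   each needs >= 2 values.
#' @param method "welch" (default) or "paired".
#' @return A one-row tibble: `statistic`, `df`, `p`, `stars`,
#'   `mean_high`, `mean_low`, `method`.
#' @export
compare_groups <- function(high, low, method = c("welch", "paired")) {
  method <- match.arg(method)
  high <- high[!is.na(high)]
  low <- low[!is.na(low)]
  if (length(high) < 2 || length(low) < 2) {
    abort("compare_groups needs >= 2 replicate values per group")
  }
  tt <- if (method == "welch") {
    if (sd(high) == 0 && sd(low) == 0 && mean(high) == mean(low)) {
      list(statistic = c(t = 0), parameter = c(df = length(high) + length(low) - 2),
           p.value = 1)
    } else {
      t.test(high, low, var.equal = FALSE)
    }
  } else {
    if (length(high) != length(low)) {
      abort("paired comparison requires equal-length, matched replicate vectors")
    }
    d <- high - low
    if (sd(d) == 0) {
      list(statistic = c(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf),
           parameter = c(df = length(d) - 1),
           p.value = if (mean(d) == 0) 1 else 0)
    } else {
      t.test(high, low, paired = TRUE)
    }
  }
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    stars = star_code(tt$p.value),
    mean_high = mean(high),
    mean_low = mean(low),
    method = method
  )
}

#' Kolmogorov-Smirnov comparison of colony size distributions
#'
#' Two-sample KS test on coral colony geometric diameters before and after
#' a disturbance: D is the maximum gap between the two empirical cumulative
#' frequency curves.
#'
#' @param sizes_pre,sizes_post Numeric vectors of colony geometric
#'   diameters; >= 5 colonies each.
#' @return A one-row tibble with `D`, `p`, `n_pre`, `n_post`.
#' @export
ks_size_comparison <- function(sizes_pre, sizes_post) {
  sizes_pre <- sizes_pre[!is.na(sizes_pre)]
  sizes_post <- sizes_post[!is.na(sizes_post)]
  if (length(sizes_pre) < 5 || length(sizes_post) < 5) {
    abort("ks_size_comparison needs >= 5 colony sizes per sample")
  }
  kt <- suppressWarnings(ks.test(sizes_pre, sizes_post))
  tibble::tibble(D = unname(kt$statistic), p = kt$p.value,
                 n_pre = length(sizes_pre), n_post = length(sizes_post))
}

#' Recovery threshold from classified sites
#'
#' The hypothesized status threshold for favourable disturbance-recovery
#' cycles: the minimum status score among sites classified "high".
#'
#' @param status Status-score tibble from [status_score()] with `site_id`
#'   and `status`.
#' @param categories Named character vector or tibble mapping `site_id` to
#'   recovery category.
#' @return Scalar threshold, or NA if no site is classified high.
#' @export
recovery_threshold <- function(status, categories) {
  if (is.data.frame(categories)) {
    cats <- setNames(categories$category, categories$site_id)
  } else {
    cats <- categories
  }
  high_sites <- names(cats)[cats == "high"]
  vals <- status$status[status$site_id %in% high_sites]
  if (length(vals) == 0) return(NA_real_)
  min(vals)
}
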