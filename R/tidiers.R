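# broom-style tidiers and ggplot2 autoplot methods.

#' @export
tidy.reef_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "(Intercept)", estimate = x$intercept,
                   se = NA_real_, statistic = NA_real_, p = NA_real_),
    x$coefficients
  )
}

#' @export
glance.reef_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_value = x$p_value, aic = x$aic,
                 n = x$n, k = x$k, label = x$label)
}

#' @export
tidy.reef_model_set <- function(x, ...) x$table

#' @export
glance.reef_model_set <- function(x, ...) {
  best <- x$table[1, ]
  tibble::tibble(n_candidates = nrow(x$table), best_model = best$model,
                 best_label = best$label, best_aic = best$aic,
                 best_r_squared = best$r_squared)
}

#' @export
tidy.reef_pca <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"species", names_to = "axis",
                      values_to = "loading")
}

#' @export
glance.reef_pca <- function(x, ...) {
  tibble::tibble(axis = paste0("PC", seq_along(x$eigenvalues)),
                 eigenvalue = x$eigenvalues,
                 var_explained = x$var_explained)
}

#' @export
tidy.reef_interaction <- function(x, ...) {
  tibble::tibble(product = x$sample)
}

#' @export
glance.reef_interaction <- function(x, ...) {
  tibble::tibble(mean = x$mean, variance = x$variance, skewness = x$skewness,
                 kurtosis = x$kurtosis, shapiro_p = x$shapiro_p,
                 n = length(x$sample), n_herb = x$n_herb, n_wq = x$n_wq)
}

#' Contour plot of a predicted-status surface
#'
#' Filled raster of predicted status over the water-quality x herbivory
#' plane with contour lines; the recovery threshold (when stored on the
#' surface) is drawn as a dashed contour.
#'
#' @param object A `reef_surface` from [build_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reef_surface <- function(object, ...) {
  thr <- attr(object, "threshold")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$wq, y = .data$herb,
                                            z = .data$predicted_status)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$predicted_status)) +
    ggplot2::geom_contour(colour = "grey30", linewidth = 0.25) +
    ggplot2::scale_fill_viridis_c(name = "Predicted\nstatus") +
    ggplot2::labs(
      x = "Water quality (standardized; larger = cleaner)",
      y = "Herbivory (standardized; larger = more herbivorous fish)",
      title = attr(object, "model_label")
    ) +
    ggplot2::theme_minimal()
  if (!is.na(thr %||% NA_real_)) {
    p <- p + ggplot2::geom_contour(breaks = thr, colour = "black",
                                   linetype = "dashed", linewidth = 0.8)
  }
  p
}

#' Ordination biplot of a species-centered PCA
#'
#' Site-year scores on the first two axes, with axis labels reporting the
#' variance fraction each axis explains.
#'
#' @param object A `reef_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reef_pca <- function(object, ...) {
  ve <- object$var_explained
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$id), vjust = -0.6,
                       size = 2.7) +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%% of variance)", 100 * ve[1]),
      y = sprintf("Axis 2 (%.1f%% of variance)",
                  100 * (if (length(ve) > 1) ve[2] else 0))
    ) +
    ggplot2::theme_minimal()
}

#' AIC ranking plot for a candidate model set
#'
#' Dot plot of delta-AIC per candidate, best model at the top.
#'
#' @param object A `reef_model_set` from [select_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reef_model_set <- function(object, ...) {
  tab <- object$table
  tab$label <- factor(tab$label, levels = rev(tab$label))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$delta_aic, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 2, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = expression(Delta * AIC), y = NULL) +
    ggplot2::theme_minimal()
}
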