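# Species-centered PCA, power-transform exponent search, power-transformed
# multiple regression and AIC model selection.

#' Species-centered principal components analysis
#'
#' Ordination of a site-year x species abundance matrix: columns are
#' centered (not scaled), and the centered matrix is decomposed so that
#' successive orthogonal axes extract as much of the community variance as
#' possible. Eigenvalues report how much of the ecological variance each
#' axis carries. Axis signs follow the convention that the
#' largest-magnitude species loading on each axis is positive.
#'
#' @param x A numeric matrix or data frame, rows = site-years (rownames or
#'   an `id` column used as labels), columns = species; no missing cells.
#' @return An object of class `reef_pca`: list with `scores` (tibble,
#'   one row per site-year, columns `id`, `PC1`, `PC2`, ...), `loadings`
#'   (tibble, one row per species), `eigenvalues`, and `var_explained`
#'   (fractions summing to 1 over all axes).
#' @export
species_centered_pca <- function(x) {
  if (is.data.frame(x)) {
    id <- if ("id" %in% names(x)) as.character(x$id) else rownames(x)
    x <- as.matrix(x[setdiff(names(x), "id")])
  } else {
    id <- rownames(x)
    x <- as.matrix(x)
  }
  if (!is.numeric(x)) abort("abundance matrix must be numeric")
  if (anyNA(x)) abort("abundance matrix must have no missing cells")
  if (nrow(x) < 2 || ncol(x) < 2) abort("need >= 2 site-years and >= 2 species")
  if (is.null(id)) id <- as.character(seq_len(nrow(x)))

  centered <- scale(x, center = TRUE, scale = FALSE)
  total_var <- sum(centered^2) / (nrow(x) - 1)
  if (total_var == 0) abort("constant abundance matrix: zero total variance")

  dec <- svd(centered)
  eig <- dec$d^2 / (nrow(x) - 1)
  k <- length(eig)
  loadings <- dec$v
  scores <- centered %*% loadings
  # sign convention: largest-magnitude loading positive on every axis
  for (j in seq_len(k)) {
    jmax <- which.max(abs(loadings[, j]))
    if (loadings[jmax, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  axis_names <- paste0("PC", seq_len(k))
  colnames(scores) <- axis_names
  colnames(loadings) <- axis_names
  structure(
    list(
      scores = dplyr::bind_cols(tibble::tibble(id = id),
                                tibble::as_tibble(scores)),
      loadings = dplyr::bind_cols(tibble::tibble(species = colnames(x)),
                                  tibble::as_tibble(loadings)),
      eigenvalues = eig,
      var_explained = eig / sum(eig)
    ),
    class = "reef_pca"
  )
}

#' @export
print.reef_pca <- function(x, ...) {
  cat(sprintf(
    "Species-centered PCA: %d site-years, %d species\n  axis 1 explains %.1f%% of the variance, axis 2 %.1f%%\n",
    nrow(x$scores), nrow(x$loadings),
    100 * x$var_explained[1],
    if (length(x$var_explained) > 1) 100 * x$var_explained[2] else 0
  ))
  invisible(x)
}

#' Default exponent grid for power-transform search
#'
#' Exponents from -10 to 10 in steps of 0.1 (201 values, exact tenths);
#' exponent 0 denotes the log transform.
#'
#' @return Numeric vector of candidate exponents.
#' @export
default_exponent_grid <- function() seq(-100L, 100L) / 10

# x^lambda with the Box-Cox-style convention that lambda = 0 means log(x).
power_transform <- function(x, lambda) {
  if (lambda == 0) log(x) else x^lambda
}

#' Search for the best power-transform exponent of a predictor
#'
#' Fits the single-term linear model `y ~ x^lambda` for every exponent on
#' the grid (lambda = 0 is `log x`) and returns the exponent minimizing the
#' Gaussian OLS AIC, `n*log(RSS/n) + 2(k+1)`. Ties are broken toward
#' lambda = 1, then toward the smaller `|lambda|`. `x` must be positive;
#' zeros are shifted by half the smallest positive value (reported via a
#' message), negatives are an error.
#'
#' @param x Predictor values (positive after the zero shift).
#' @param y Response values.
#' @param grid Candidate exponents; default [default_exponent_grid()].
#' @return A list with `exponent`, `aic`, `offset` (zero-shift applied, 0 if
#'   none), `flagged` (TRUE when the response is constant and the search is
#'   meaningless), and `aic_table` (tibble of exponent and AIC).
#' @export
power_search <- function(x, y, grid = default_exponent_grid()) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) abort("power_search needs >= 4 complete observations")
  if (any(x < 0)) abort("predictor has negative values; power transforms undefined")
  offset <- 0
  if (any(x == 0)) {
    pos <- x[x > 0]
    if (length(pos) == 0) abort("predictor is identically zero")
    offset <- min(pos) / 2
    inform(sprintf("power_search: %d zero value(s) shifted by offset %g",
                   sum(x == 0), offset))
    x <- x + offset
  }
  if (sd(y) == 0) {
    warn("power_search: constant response; exponent 1 returned with zero slope (flagged)")
    return(list(exponent = 1, aic = NA_real_, offset = offset, flagged = TRUE,
                aic_table = tibble::tibble(exponent = grid, aic = NA_real_)))
  }
  n <- length(x)
  aics <- vapply(grid, function(lam) {
    tx <- power_transform(x, lam)
    if (!all(is.finite(tx)) || sd(tx) == 0) return(Inf)
    fit <- lm.fit(cbind(1, tx), y)
    rss <- sum(fit$residuals^2)
    n * log(rss / n) + 2 * (1 + 1)
  }, numeric(1))
  best <- min(aics)
  # tie band at numerical resolution; prefer lambda = 1, then smaller |lambda|
  tied <- which(aics <= best + 1e-8)
  pick <- if (any(grid[tied] == 1)) tied[grid[tied] == 1][1] else {
    tied[order(abs(grid[tied]), abs(grid[tied] - 1))][1]
  }
  list(exponent = grid[pick], aic = aics[pick], offset = offset,
       flagged = FALSE, aic_table = tibble::tibble(exponent = grid, aic = aics))
}

# --- model terms -------------------------------------------------------------

#' Construct a regression term: a power-transformed variable or a product
#'
#' Terms mirror the candidate-model vocabulary of the island-wide
#' regressions: a single transformed variable (`pow_term("dist_land",
#' -0.6)`), or the product of two transformed variables
#' (`pow_term(c("shed_area", "wave_exposure"), c(10, -3.2))`). Exponent 0
#' denotes the log transform.
#'
#' @param vars Character vector of 1 or 2 variable names.
#' @param exps Numeric exponents, recycled to `length(vars)`; default 1.
#' @return A `reef_term` list with elements `vars` and `exps`.
#' @export
pow_term <- function(vars, exps = 1) {
  if (!length(vars) %in% c(1L, 2L)) abort("a term holds 1 or 2 variables")
  exps <- rep_len(exps, length(vars))
  structure(list(vars = vars, exps = exps), class = "reef_term")
}

term_label <- function(term) {
  paste(purrr::map2_chr(term$vars, term$exps, function(v, e) {
    if (e == 0) sprintf("log(%s)", v)
    else if (e == 1) v
    else sprintf("%s^%g", v, e)
  }), collapse = " * ")
}

term_column <- function(term, data) {
  cols <- purrr::map2(term$vars, term$exps, function(v, e) {
    if (!v %in% names(data)) abort(sprintf("variable '%s' not found in data", v))
    x <- data[[v]]
    if (e != 1 && e != round(e) && any(x < 0, na.rm = TRUE)) {
      abort(sprintf("variable '%s' has negative values; fractional exponent undefined", v))
    }
    if (e <= 0 && any(x == 0, na.rm = TRUE)) {
      abort(sprintf("variable '%s' has zeros; exponent %g undefined", v, e))
    }
    power_transform(x, e)
  })
  purrr::reduce(cols, `*`)
}

#' Fit one candidate regression model
#'
#' Ordinary least squares of the response on at most two power-transformed
#' single-variable terms plus at most one product of two transformed
#' variables, matching the candidate forms of the island-wide analysis. Reports slopes with standard errors,
#' intercept, R-squared, the overall-F p-value, and the Gaussian OLS
#' AIC = n*log(RSS/n) + 2(k+1). An empty term list fits the intercept-only
#' baseline.
#'
#' @param data A data frame holding the response and raw predictors.
#' @param response Name of the response column.
#' @param terms A list of [pow_term()] objects (0 to 2 of them).
#' @return An object of class `reef_model` (supports [tidy()], [glance()],
#'   [predict()]): list with `label`, `terms`, `coefficients` (tibble),
#'   `intercept`, `r_squared`, `p_value`, `aic`, `n`, `k`, `fit`.
#' @export
fit_model <- function(data, response, terms = list()) {
  if (inherits(terms, "reef_term")) terms <- list(terms)
  n_single <- sum(vapply(terms, function(t) length(t$vars) == 1, logical(1)))
  n_prod <- length(terms) - n_single
  if (n_single > 2 || n_prod > 1) {
    abort("candidate models hold at most 2 single terms plus 1 product term")
  }
  if (!response %in% names(data)) {
    abort(sprintf("response '%s' not found in data", response))
  }
  y <- data[[response]]
  design <- if (length(terms) == 0) {
    tibble::tibble(.rows = length(y))
  } else {
    cols <- purrr::map(terms, term_column, data = data)
    names(cols) <- paste0("t", seq_along(cols))
    tibble::as_tibble(cols)
  }
  keep <- stats::complete.cases(design) & !is.na(y)
  design <- design[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  k <- length(terms)
  if (n <= k + 2) abort(sprintf("need n > k + 2 observations (n = %d, k = %d)", n, k))

  df_fit <- dplyr::bind_cols(tibble::tibble(.y = y), design)
  fml <- if (k == 0) .y ~ 1 else {
    stats::as.formula(paste(".y ~", paste(names(design), collapse = " + ")))
  }
  fit <- lm(fml, data = df_fit)
  if (fit$rank < k + 1) abort("rank-deficient design (collinear or constant terms)")
  sm <- summary(fit)
  rss <- sum(fit$residuals^2)
  aic <- n * log(rss / n) + 2 * (k + 1)
  labels <- vapply(terms, term_label, character(1))
  coefs <- if (k == 0) {
    tibble::tibble(term = character(), estimate = numeric(), se = numeric(),
                   statistic = numeric(), p = numeric())
  } else {
    ct <- sm$coefficients[-1, , drop = FALSE]
    tibble::tibble(term = labels, estimate = ct[, 1], se = ct[, 2],
                   statistic = ct[, 3], p = ct[, 4])
  }
  p_overall <- if (k == 0) NA_real_ else {
    f <- sm$fstatistic
    unname(pf(f[1], f[2], f[3], lower.tail = FALSE))
  }
  structure(
    list(
      label = if (k == 0) "(intercept only)" else paste(labels, collapse = " + "),
      terms = terms,
      coefficients = coefs,
      intercept = unname(coef(fit)[1]),
      r_squared = if (k == 0) 0 else sm$r.squared,
      p_value = p_overall,
      aic = aic,
      n = n,
      k = k,
      fit = fit
    ),
    class = "reef_model"
  )
}

#' @export
print.reef_model <- function(x, ...) {
  cat(sprintf("Model: %s\n  n = %d, R^2 = %.3f, p = %s, AIC = %.2f\n",
              x$label, x$n, x$r_squared,
              ifelse(is.na(x$p_value), "NA", format.pval(x$p_value, digits = 3)),
              x$aic))
  if (nrow(x$coefficients) > 0) print(x$coefficients)
  cat(sprintf("  intercept %.4g\n", x$intercept))
  invisible(x)
}

#' Predict from a fitted candidate model
#'
#' @param object A `reef_model`.
#' @param newdata Data frame holding the raw (untransformed) predictor
#'   columns used by the model's terms.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.reef_model <- function(object, newdata, ...) {
  if (object$k == 0) return(rep(object$intercept, nrow(newdata)))
  cols <- purrr::map(object$terms, term_column, data = newdata)
  names(cols) <- paste0("t", seq_along(cols))
  predict(object$fit, newdata = tibble::as_tibble(cols))
}

#' Rank candidate models by AIC
#'
#' Fits every candidate on an identical row set (listwise deletion over the
#' union of all candidate variables and the response, applied before any
#' fit) and ranks them by ascending AIC; ties keep declaration order.
#'
#' @param data Data frame of response and raw predictors.
#' @param response Response column name.
#' @param candidates A named (or unnamed) list of candidates, each a list of
#'   [pow_term()] objects (possibly empty for the intercept-only baseline).
#' @return An object of class `reef_model_set`: list with `table` (tibble
#'   ranked by AIC: rank, model, label, k, r_squared, p_value, aic,
#'   delta_aic) and `models` (fitted `reef_model`s in declaration order).
#' @export
select_model <- function(data, response, candidates) {
  if (length(candidates) == 0) abort("empty candidate set")
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    names(candidates) <- paste0("M", seq_along(candidates))
  }
  all_vars <- unique(c(response, unlist(purrr::map(
    candidates, function(cand) unlist(purrr::map(cand, "vars"))
  ))))
  missing <- setdiff(all_vars, names(data))
  if (length(missing) > 0) {
    abort(sprintf("variables not found in data: %s", paste(missing, collapse = ", ")))
  }
  rows <- stats::complete.cases(data[all_vars])
  data <- data[rows, , drop = FALSE]

  models <- purrr::map(candidates, function(cand) fit_model(data, response, cand))
  tab <- tibble::tibble(
    model = names(candidates),
    label = unname(purrr::map_chr(models, "label")),
    k = unname(purrr::map_int(models, "k")),
    r_squared = unname(purrr::map_dbl(models, "r_squared")),
    p_value = unname(purrr::map_dbl(models,
                                    function(m) m$p_value %||% NA_real_)),
    aic = unname(purrr::map_dbl(models, "aic"))
  )
  ord <- order(tab$aic)  # stable: ties keep declaration order
  tab <- tab[ord, ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$rank <- seq_len(nrow(tab))
  tab <- dplyr::relocate(tab, "rank")
  structure(list(table = tab, models = models), class = "reef_model_set")
}

#' @export
print.reef_model_set <- function(x, ...) {
  cat("Candidate models ranked by AIC:\n")
  print(x$table)
  invisible(x)
}

#' Enumerate the island-wide candidate model space
#'
#' Builds the candidate set used for the spatial regressions: every single
#' transformed variable, every two-variable additive pair, every
#' two-variable product, plus the intercept-only baseline. Per-variable
#' exponents are chosen greedily beforehand with [power_search()] against
#' the response (pass `exponents` to override or skip the search with
#' `search_exponents = FALSE`, which leaves every exponent at 1).
#'
#' @param data Data frame of response and predictors.
#' @param response Response column name.
#' @param independents Character vector of predictor names.
#' @param search_exponents Run the per-variable exponent search? Default
#'   TRUE; requires strictly positive predictors (zeros are shifted, see
#'   [power_search()]).
#' @param exponents Optional named numeric vector of exponents per
#'   predictor, bypassing the search.
#' @param include_products Include two-variable product candidates? Default
#'   TRUE.
#' @return A named list of candidates suitable for [select_model()].
#' @export
enumerate_candidates <- function(data, response, independents,
                                 search_exponents = TRUE, exponents = NULL,
                                 include_products = TRUE) {
  if (length(independents) < 1) abort("need >= 1 independent variable")
  if (is.null(exponents)) {
    exponents <- setNames(rep(1, length(independents)), independents)
    if (search_exponents) {
      for (v in independents) {
        ps <- power_search(data[[v]], data[[response]])
        exponents[[v]] <- if (ps$flagged) 1 else ps$exponent
      }
    }
  } else {
    missing <- setdiff(independents, names(exponents))
    exponents[missing] <- 1
  }
  singles <- lapply(independents, function(v) list(pow_term(v, exponents[[v]])))
  names(singles) <- independents
  cands <- c(list(`(null)` = list()), singles)
  if (length(independents) >= 2) {
    pairs <- utils::combn(independents, 2, simplify = FALSE)
    sums <- lapply(pairs, function(p) {
      list(pow_term(p[1], exponents[[p[1]]]), pow_term(p[2], exponents[[p[2]]]))
    })
    names(sums) <- vapply(pairs, paste, character(1), collapse = " + ")
    cands <- c(cands, sums)
    if (include_products) {
      prods <- lapply(pairs, function(p) {
        list(pow_term(p, c(exponents[[p[1]]], exponents[[p[2]]])))
      })
      names(prods) <- vapply(pairs, paste, character(1), collapse = " x ")
      cands <- c(cands, prods)
    }
  }
  cands
}
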