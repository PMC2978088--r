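# PCA, power-transform search, regression fitting and AIC selection.

test_that("species-centered PCA matches a covariance eigendecomposition", {
  set.seed(3)
  x <- matrix(rnorm(24), nrow = 6, ncol = 4,
              dimnames = list(NULL, paste0("sp", 1:4)))
  p <- species_centered_pca(x)
  oracle <- eigen(stats::cov(x), symmetric = TRUE)
  keep <- oracle$values > 1e-12
  expect_equal(p$eigenvalues[seq_len(sum(keep))], oracle$values[keep],
               tolerance = 1e-9)
  expect_equal(sum(p$var_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(p$var_explained) <= 1e-12))

  # reconstruction from all axes is exact
  scores <- as.matrix(p$scores[-1])
  loadings <- as.matrix(p$loadings[-1])
  centered <- scale(x, center = TRUE, scale = FALSE)
  expect_equal(scores %*% t(loadings), unclass(centered),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("PCA handles forced and degenerate structures", {
  r1 <- outer(c(1, 2, 3, 5), c(2, 1, 0.5))
  colnames(r1) <- paste0("sp", 1:3)
  p <- species_centered_pca(r1)
  expect_equal(p$var_explained[1], 1, tolerance = 1e-12)

  dup <- rbind(r1, r1)
  pd <- species_centered_pca(dup)
  expect_equal(unlist(pd$scores[1, -1]), unlist(pd$scores[5, -1]),
               tolerance = 1e-9)

  # sign convention: the largest-magnitude loading is positive
  expect_true(all(vapply(p$loadings[-1],
                         function(l) l[which.max(abs(l))] > 0, logical(1))))

  expect_error(species_centered_pca(matrix(1, 4, 3)), "zero total variance")
  expect_error(species_centered_pca(matrix(1:4, 1)), ">= 2")
})

test_that("power_search recovers generating exponents", {
  set.seed(17)
  x <- runif(40, 0.5, 3)
  expect_equal(power_search(x, 2 + 3 * x)$exponent, 1)
  expect_equal(power_search(x, x^-0.6)$exponent, -0.6)
  expect_equal(power_search(x, 5 * log(x) - 1)$exponent, 0)
  expect_warning(ps <- power_search(x, rep(2, 40)), "constant response")
  expect_true(ps$flagged)
  expect_equal(ps$exponent, 1)
  expect_error(power_search(c(-1, x[-1]), x), "negative")
  xz <- c(0, x[-1])
  expect_message(psz <- power_search(xz, 1 + xz), "shifted")
  expect_gt(psz$offset, 0)
})

test_that("fit_model reports exact OLS results and the stated AIC", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  m <- fit_model(d, "y", list(pow_term("x")))
  expect_equal(m$coefficients$estimate, 2, tolerance = 1e-9)
  expect_equal(m$intercept, 1, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)

  # AIC = n log(RSS/n) + 2(k+1), reproduced bit-for-bit on refit
  set.seed(2)
  d2 <- tibble::tibble(x = rnorm(20), y = rnorm(20))
  m2 <- fit_model(d2, "y", list(pow_term("x")))
  rss <- sum(residuals(m2$fit)^2)
  expect_identical(m2$aic, 20 * log(rss / 20) + 2 * 2)
  m2b <- fit_model(d2, "y", list(pow_term("x")))
  expect_identical(m2$aic, m2b$aic)

  # intercept-only baseline
  m0 <- fit_model(d2, "y", list())
  expect_equal(m0$k, 0)
  expect_equal(m0$intercept, mean(d2$y))

  expect_error(fit_model(d2[1:3, ], "y", list(pow_term("x"))), "n > k")
  d2$x2 <- d2$x
  expect_error(fit_model(d2, "y", list(pow_term("x"), pow_term("x2"))),
               "rank-deficient")
  expect_error(
    fit_model(d2, "y", list(pow_term("x"), pow_term("x2"), pow_term("x"))),
    "at most 2 single terms")
})

test_that("fit_model recovers simulated slopes within 2 SE", {
  # noise-controlled parameter recovery at the monitoring-design sample size
  set.seed(71)
  est <- t(replicate(500, {
    d <- tibble::tibble(x1 = rnorm(17), x2 = rnorm(17))
    d$y <- 2.5 * d$x1 - 1.9 * d$x2 + rnorm(17, 0, 0.5)
    fit_model(d, "y", list(pow_term("x1"), pow_term("x2")))$coefficients$estimate
  }))
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - 2.5), 2 * se[1])
  expect_lt(abs(mean(est[, 2]) + 1.9), 2 * se[2])
})

test_that("tidy and glance expose broom-style summaries", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  m <- fit_model(d, "y", list(pow_term("x")))
  td <- tidy(m)
  expect_equal(td$term, c("(Intercept)", "x"))
  g <- glance(m)
  expect_equal(g$n, 10)
  expect_equal(g$r_squared, 1, tolerance = 1e-12)
})

test_that("select_model ranks by AIC with stable ties and listwise deletion", {
  set.seed(4)
  d <- tibble::tibble(x1 = rnorm(20), x2 = rnorm(20))
  d$y <- 1.5 * d$x1 + rnorm(20, 0, 0.1)
  sel <- select_model(d, "y", list(a = list(pow_term("x1")),
                                   b = list(pow_term("x2")),
                                   a2 = list(pow_term("x1"))))
  expect_equal(sel$table$model[1], "a")          # declaration order on ties
  expect_equal(sel$table$aic[1], sel$table$aic[2])
  expect_equal(sel$table$delta_aic[1], 0)

  # rows with missing values anywhere are dropped before every fit
  d$x2[3] <- NA
  sel2 <- select_model(d, "y", list(a = list(pow_term("x1")),
                                    b = list(pow_term("x2"))))
  expect_true(all(vapply(sel2$models, function(m) m$n, numeric(1)) == 19))

  expect_error(select_model(d, "y", list()), "empty candidate set")
})

test_that("AIC selection recovers the generating candidate as noise vanishes", {
  set.seed(9)
  cands <- list(single = list(pow_term("x1")),
                additive = list(pow_term("x1"), pow_term("x2")),
                product = list(pow_term(c("x1", "x2"))))
  hits <- vapply(1:20, function(i) {
    d <- tibble::tibble(x1 = rnorm(17), x2 = rnorm(17))
    d$y <- 2 * d$x1 * d$x2 + rnorm(17, 0, 1e-6)
    select_model(d, "y", cands)$table$model[1] == "product"
  }, logical(1))
  expect_true(all(hits))
})

test_that("a pure-noise response keeps the intercept-only baseline near the top", {
  set.seed(27)
  near_top <- vapply(1:40, function(i) {
    d <- tibble::tibble(x1 = rnorm(17), x2 = rnorm(17), y = rnorm(17))
    sel <- select_model(d, "y", list(`(null)` = list(),
                                     x1 = list(pow_term("x1")),
                                     x2 = list(pow_term("x2")),
                                     both = list(pow_term("x1"), pow_term("x2"))))
    sel$table$delta_aic[sel$table$model == "(null)"] <= 2
  }, logical(1))
  expect_gt(mean(near_top), 0.5)
})

test_that("enumerate_candidates spans singles, sums and products", {
  set.seed(5)
  d <- tibble::tibble(a = runif(12, 1, 3), b = runif(12, 1, 3),
                      c = runif(12, 1, 3))
  d$y <- d$a + rnorm(12, 0, 0.1)
  cands <- enumerate_candidates(d, "y", c("a", "b", "c"),
                                search_exponents = FALSE)
  # null + 3 singles + 3 sums + 3 products
  expect_equal(length(cands), 10)
  expect_true("(null)" %in% names(cands))
  expect_true(all(c("a + b", "a x b") %in% names(cands)))
  sel <- select_model(d, "y", cands)
  # at n = 12 AIC may admit one junk term alongside the true one
  expect_true(grepl("a", sel$table$model[1]))
})
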