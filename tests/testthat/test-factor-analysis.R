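test_that("KMO equals 0.5 for two correlated features and matches a regression oracle", {
  # with two variables the partial correlation equals the correlation, so
  # the numerator is exactly half the denominator
  tbl <- random_feature_table(30, 2, seed = 1)
  tbl$f2 <- tbl$f2 + 0.5 * tbl$f1
  expect_equal(kmo(tbl)$kmo, 0.5, tolerance = 1e-12)

  # 4-feature table: anti-image partial correlations recomputed independently
  # from regression residuals
  tbl4 <- random_feature_table(40, 4, seed = 7)
  tbl4$f2 <- tbl4$f2 + 0.6 * tbl4$f1
  tbl4$f4 <- tbl4$f4 - 0.4 * tbl4$f3 + 0.3 * tbl4$f1
  x <- as.matrix(tbl4)
  p <- ncol(x)
  partial <- matrix(NA_real_, p, p)
  for (i in 1:p) for (j in 1:p) {
    if (i >= j) next
    others <- x[, -c(i, j), drop = FALSE]
    ri <- resid(lm(x[, i] ~ others))
    rj <- resid(lm(x[, j] ~ others))
    partial[i, j] <- cor(ri, rj)
  }
  R <- cor(x)
  off <- upper.tri(R)
  expected <- sum(R[off]^2) / (sum(R[off]^2) + sum(partial[off]^2, na.rm = TRUE))
  expect_equal(kmo(tbl4)$kmo, expected, tolerance = 1e-8)
  expect_true(kmo(tbl4)$kmo >= 0 && kmo(tbl4)$kmo <= 1)

  # duplicated feature: singular correlation matrix
  dup <- tbl4
  dup$f5 <- dup$f1
  expect_error(kmo(dup), class = "frostgrade_error_collinear")
})

test_that("Bartlett sphericity matches the closed form and degenerates are caught", {
  # exactly uncorrelated features: det(R) = 1, statistic 0, p-value 1
  R_id <- diag(3)
  tbl <- table_with_exact_correlation(12, R_id, seed = 2)
  bt <- bartlett_sphericity(tbl)
  expect_equal(bt$statistic, 0, tolerance = 1e-10)
  expect_equal(bt$p_value, 1, tolerance = 1e-10)

  # n = 10, p = 3, all off-diagonal correlations 0.5: det(R) = 0.5 and
  # statistic = -(9 - 11/6) ln 0.5
  R5 <- matrix(0.5, 3, 3); diag(R5) <- 1
  tbl5 <- table_with_exact_correlation(10, R5, seed = 3)
  bt5 <- bartlett_sphericity(tbl5)
  expect_equal(bt5$statistic, -(9 - 11 / 6) * log(0.5), tolerance = 1e-8)
  expect_equal(bt5$df, 3)

  # perfectly collinear pair -> error
  col <- tibble::tibble(a = rnorm(10))
  col$b <- 2 * col$a
  col$c <- rnorm(10)
  expect_error(bartlett_sphericity(col), class = "frostgrade_error_degenerate")
})

test_that("factor extraction keeps the contribution bookkeeping consistent", {
  tbl <- random_feature_table(60, 8, seed = 11)
  # plant some correlation so eigenvalue > 1 retention succeeds
  tbl <- dplyr::mutate(tbl, f2 = f1 + 0.5 * f2, f3 = f1 - 0.5 * f3,
                       f5 = f4 + 0.6 * f5)
  fm <- suppressWarnings(extract_factors(tbl))
  expect_equal(sum(fm$eigenvalues), 8, tolerance = 1e-8)
  full_vdr <- 100 * fm$eigenvalues / 8
  expect_equal(sum(full_vdr), 100, tolerance = 1e-8)
  expect_equal(fm$cdr, cumsum(fm$vdr), tolerance = 1e-10)
  expect_true(all(diff(fm$cdr) >= 0))

  # varimax rotation preserves each feature's communality
  eig <- eigen(cor(as.matrix(tbl)), symmetric = TRUE)
  L_unrot <- eig$vectors[, seq_len(fm$m), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(fm$m)]), fm$m)
  expect_equal(rowSums(fm$loadings^2), unname(rowSums(L_unrot^2)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # exactly isotropic features: no eigenvalue exceeds 1 -> retention error
  iso <- table_with_exact_correlation(40, diag(6), seed = 5)
  expect_error(suppressWarnings(extract_factors(iso)),
               class = "frostgrade_error_retention")
  fixed <- suppressWarnings(extract_factors(iso, retention = "fixed", m = 2))
  expect_equal(fixed$m, 2)
})

test_that("a planted two-factor structure is recovered up to sign and permutation", {
  loadings <- cbind(c(0.9, 0.85, 0.8, 0, 0, 0),
                    c(0, 0, 0, 0.9, 0.85, 0.8))
  x <- withr::with_seed(42, {
    f <- matrix(rnorm(200 * 2), 200, 2)
    f %*% t(loadings) + matrix(rnorm(200 * 6, sd = sqrt(1 - 0.85^2)), 200, 6)
  })
  colnames(x) <- paste0("f", 1:6)
  fm <- suppressWarnings(extract_factors(tibble::as_tibble(x)))
  expect_equal(fm$m, 2)
  L <- fm$loadings
  # align columns/signs to the planted structure
  perm <- if (abs(L[1, 1]) > abs(L[1, 2])) 1:2 else 2:1
  L <- L[, perm]
  for (j in 1:2) if (sum(L[, j] * loadings[, j]) < 0) L[, j] <- -L[, j]
  expect_lt(max(abs(L - loadings)), 0.1)
})

test_that("score coefficients reproduce the reference worked example", {
  # the two retained composite factors carry variance contributions
  # 74.815% and 13.757% (cumulative 88.572%)
  fm <- factor_model(
    features = c("G_Skewness", "R_Kurtosis"),
    vdr = c(74.815, 13.757), cdr = c(74.815, 88.572),
    scores = rbind(c(-0.195, 0.141), c(0.155, -0.226))
  )
  sc <- score_coefficients(fm)
  expect_equal(round(sc$coef_1, 3), c(-0.165, 0.131))
  expect_equal(round(sc$coef_2, 3), c(0.022, -0.035))
  expect_equal(round(sc$abs_fsc, 3), c(0.143, 0.096))

  # a single retained factor: weight 1, coefficients equal the scores
  fm1 <- factor_model(features = c("a", "b"), vdr = 80, cdr = 80,
                      scores = cbind(c(0.3, -0.2)))
  sc1 <- score_coefficients(fm1)
  expect_equal(sc1$coef_1, c(0.3, -0.2))
  expect_equal(sc1$fsc, c(0.3, -0.2))

  # literal product mode, contributions as fractions
  sc_eq1 <- score_coefficients(fm, mode = "eq1")
  w <- (c(74.815, 13.757) / 100) * (c(74.815, 88.572) / 100)
  expect_equal(sc_eq1$fsc[1], sum(c(-0.195, 0.141) * w), tolerance = 1e-12)
})

test_that("key-parameter selection ranks by |FSC| with deterministic ties", {
  scores <- tibble::tibble(
    feature = c("b", "a", "c", "d"),
    fsc = c(0.5, -0.5, 0.2, 0.9),
    abs_fsc = c(0.5, 0.5, 0.2, 0.9)
  )
  class(scores) <- c("key_parameter_scores", class(scores))
  expect_equal(select_key_parameters(scores, k = 3), c("d", "a", "b"))
  # invariant to row order
  expect_equal(select_key_parameters(scores[c(3, 1, 4, 2), ], k = 3),
               c("d", "a", "b"))
  expect_equal(select_key_parameters(scores, k = 4), c("d", "a", "b", "c"))
  expect_error(select_key_parameters(scores, k = 0), class = "frostgrade_error_arg")
  expect_error(select_key_parameters(scores, k = 9), class = "frostgrade_error_arg")
})
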