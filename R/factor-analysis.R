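#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO of a samples-by-features table:
#' `KMO = sum(r^2) / (sum(r^2) + sum(p^2))` over the off-diagonal elements of
#' the correlation matrix `R` and of the anti-image partial-correlation matrix
#' `P` (with `P[ij] = -Rinv[ij] / sqrt(Rinv[ii] Rinv[jj])`). Values above 0.7
#' qualify the table for factor analysis.
#'
#' @param data A data frame of samples by features (metadata columns such as
#'   `sample_id` and `grade` are ignored).
#' @param features Optional character vector naming the feature columns.
#' @param threshold Pass threshold (default 0.7).
#' @return A one-row tibble with columns `kmo`, `pass`, `n`, `p`.
#' @export
kmo <- function(data, features = NULL, threshold = 0.7) {
  x <- feature_matrix(data, features)
  R <- correlation_or_die(x)
  Rinv <- tryCatch(solve(R), error = function(e) {
    abort_collinear(R)
  })
  P <- -Rinv / sqrt(outer(diag(Rinv), diag(Rinv)))
  off <- upper.tri(R)
  value <- sum(R[off]^2) / (sum(R[off]^2) + sum(P[off]^2))
  tibble::tibble(kmo = value, pass = value > threshold,
                 n = nrow(x), p = ncol(x))
}

#' Bartlett's test of sphericity
#'
#' Chi-square test that the feature correlation matrix is the identity:
#' `statistic = -(n - 1 - (2p + 5) / 6) * log(det(R))` with
#' `df = p (p - 1) / 2`. A p-value below 0.05 is required before factoring.
#'
#' @inheritParams kmo
#' @param alpha Significance threshold for the pass flag (default 0.05).
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `pass`.
#' @export
bartlett_sphericity <- function(data, features = NULL, alpha = 0.05) {
  x <- feature_matrix(data, features)
  n <- nrow(x); p <- ncol(x)
  R <- correlation_or_die(x)
  # log-determinant via eigenvalues: near-singular CGSD correlation matrices
  # (smallest eigenvalues ~1e-5) underflow det() long before they are truly
  # degenerate
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) <= 1e-12) {
    abort("correlation matrix is degenerate (collinear features)",
          class = "frostgrade_error_degenerate")
  }
  stat <- -(n - 1 - (2 * p + 5) / 6) * sum(log(lambda))
  df <- p * (p - 1) / 2
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 pass = pchisq(stat, df, lower.tail = FALSE) < alpha)
}

correlation_or_die <- function(x) {
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance feature(s): ",
                 paste(colnames(x)[sds == 0], collapse = ", ")),
          class = "frostgrade_error_collinear")
  }
  cor(x)
}

abort_collinear <- function(R) {
  off <- which(abs(R) > 1 - 1e-10 & upper.tri(R), arr.ind = TRUE)
  pairs <- apply(off, 1, function(ij) {
    paste(colnames(R)[ij[1]], colnames(R)[ij[2]], sep = " ~ ")
  })
  msg <- "correlation matrix is singular"
  if (length(pairs) > 0) {
    msg <- paste0(msg, "; collinear feature pair(s): ", paste(pairs, collapse = ", "))
  }
  abort(msg, class = "frostgrade_error_collinear")
}

#' Construct a factor model
#'
#' Low-level constructor for the result of a factor extraction: eigenvalues of
#' the feature correlation matrix, per-factor variance contributions (VDR, %),
#' cumulative contributions (CDR, %), rotated loadings and regression-method
#' score coefficients (SC) for the `m` retained factors. Normally produced by
#' [extract_factors()], but can be assembled directly, e.g. from a reported
#' factor table.
#'
#' @param features Character vector of feature names (length p).
#' @param eigenvalues Numeric vector of all p eigenvalues, descending, or
#'   `NULL` if only the retained factors are known.
#' @param vdr Variance contribution (%) of each retained factor.
#' @param cdr Cumulative contribution (%) through each retained factor
#'   (defaults to `cumsum(vdr)`).
#' @param loadings p x m matrix of rotated loadings, or `NULL`.
#' @param scores p x m matrix of factor score coefficients SC.
#' @param screening Optional tibble recording KMO / Bartlett screening.
#' @return An object of class `factor_model`.
#' @export
factor_model <- function(features, vdr, scores, cdr = cumsum(vdr),
                         eigenvalues = NULL, loadings = NULL,
                         screening = NULL) {
  m <- length(vdr)
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(features), ncol(scores) == m,
            length(cdr) == m)
  dimnames(scores) <- list(features, paste0("factor_", seq_len(m)))
  if (!is.null(loadings)) {
    loadings <- as.matrix(loadings)
    stopifnot(all(dim(loadings) == dim(scores)))
    dimnames(loadings) <- dimnames(scores)
  }
  structure(
    list(features = features, eigenvalues = eigenvalues,
         vdr = vdr, cdr = cdr, m = m,
         loadings = loadings, scores = scores, screening = screening),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d features, %d retained factor(s)\n",
              length(x$features), x$m))
  cat(sprintf("  VDR (%%): %s\n", paste(round(x$vdr, 3), collapse = ", ")))
  cat(sprintf("  CDR through factor %d: %.3f%%\n", x$m, x$cdr[x$m]))
  invisible(x)
}

#' Extract and rotate composite factors from a feature table
#'
#' Principal-component style factor analysis of the feature correlation
#' matrix: eigendecomposition, retention of factors with eigenvalue > 1 (or a
#' fixed count), varimax rotation of the retained loadings, and
#' regression-method score coefficients `SC = solve(R) %*% L_rotated`.
#' Variance contributions `VDR_j = 100 * lambda_j / p` and their cumulative
#' sums CDR are reported on the unrotated eigenvalues.
#'
#' @inheritParams kmo
#' @param retention `"eigenvalue"` (retain eigenvalues > 1, the default) or
#'   `"fixed"` (retain `m` factors).
#' @param m Number of factors when `retention = "fixed"`.
#' @param rotate `"varimax"` (default) or `"none"`.
#' @param screen Run KMO and Bartlett screening and warn on failure
#'   (default `TRUE`).
#' @return A [factor_model()].
#' @export
extract_factors <- function(data, features = NULL,
                            retention = c("eigenvalue", "fixed"), m = NULL,
                            rotate = c("varimax", "none"), screen = TRUE) {
  retention <- match.arg(retention)
  rotate <- match.arg(rotate)
  x <- feature_matrix(data, features)
  p <- ncol(x)
  R <- correlation_or_die(x)
  screening <- NULL
  if (screen) {
    km <- kmo(data, features = colnames(x))
    bt <- bartlett_sphericity(data, features = colnames(x))
    screening <- tibble::tibble(test = c("KMO", "Bartlett"),
                                value = c(km$kmo, bt$statistic),
                                p_value = c(NA_real_, bt$p_value),
                                pass = c(km$pass, bt$pass))
    if (!km$pass) warn(sprintf("KMO %.3f below 0.7; factoring may be unreliable", km$kmo))
    if (!bt$pass) warn("Bartlett sphericity test not significant; factoring may be unreliable")
  }
  eig <- eigen(R, symmetric = TRUE)
  lambda <- eig$values
  if (retention == "eigenvalue") {
    m_keep <- sum(lambda > 1 + 1e-8) # tolerance guards the isotropic case
    if (m_keep == 0) {
      abort("no eigenvalue exceeds 1; use retention = \"fixed\" with an explicit m",
            class = "frostgrade_error_retention")
    }
  } else {
    if (is.null(m) || m < 1 || m > p) {
      abort("retention = \"fixed\" needs m between 1 and the feature count",
            class = "frostgrade_error_arg")
    }
    m_keep <- m
  }
  L <- eig$vectors[, seq_len(m_keep), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(m_keep)]), m_keep)
  # orient each factor so its largest-magnitude loading is positive
  for (j in seq_len(m_keep)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  if (rotate == "varimax" && m_keep > 1) {
    rot <- varimax(L, normalize = TRUE)
    L <- L %*% rot$rotmat
  }
  SC <- solve(R, L)
  vdr <- 100 * lambda / p
  fm <- factor_model(features = colnames(x),
                     vdr = vdr[seq_len(m_keep)],
                     cdr = cumsum(vdr)[seq_len(m_keep)],
                     scores = SC, eigenvalues = lambda, loadings = L,
                     screening = screening)
  fm
}

#' @describeIn extract_factors Tidy the loadings and score coefficients into a
#'   long tibble with columns `feature`, `factor`, `loading`, `score`.
#' @param x A `factor_model`.
#' @param ... Unused.
#' @export
tidy.factor_model <- function(x, ...) {
  m <- x$m
  tibble::tibble(
    feature = rep(x$features, times = m),
    factor = rep(seq_len(m), each = length(x$features)),
    loading = if (is.null(x$loadings)) NA_real_ else as.vector(x$loadings),
    score = as.vector(x$scores)
  )
}

#' @describeIn extract_factors One-row summary: feature count, retained-factor
#'   count, cumulative contribution of the retained set.
#' @export
glance.factor_model <- function(x, ...) {
  tibble::tibble(p = length(x$features), m = x$m, cdr_retained = x$cdr[x$m])
}

#' Principal-component score coefficients and combined scores
#'
#' Combines each feature's factor score coefficients into a single ranking
#' score FSC. In the default `"table10"` mode each retained factor's score is
#' weighted by its variance contribution normalized by the cumulative
#' contribution of the retained set: `FSC_i = sum_j SC_ij * VDR_j / CDR_m`.
#' The `"eq1"` mode applies the literal product form
#' `FSC_i = sum_j (VDR_j/100) * (CDR_j/100) * SC_ij` for comparison.
#'
#' @param model A [factor_model()].
#' @param mode `"table10"` (default) or `"eq1"`.
#' @return A tibble of class `key_parameter_scores` with one row per feature:
#'   per-factor coefficient columns `coef_1..coef_m`, the combined score
#'   `fsc`, and `abs_fsc`.
#' @export
score_coefficients <- function(model, mode = c("table10", "eq1")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "factor_model"))
  w <- switch(mode,
    table10 = model$vdr / model$cdr[model$m],
    eq1 = (model$vdr / 100) * (model$cdr / 100)
  )
  coef <- sweep(model$scores, 2, w, `*`)
  out <- tibble::as_tibble(coef, .name_repair = ~ paste0("coef_", seq_along(.x)))
  out <- dplyr::bind_cols(tibble::tibble(feature = model$features), out)
  out$fsc <- unname(rowSums(coef))
  out$abs_fsc <- abs(out$fsc)
  class(out) <- c("key_parameter_scores", class(out))
  attr(out, "mode") <- mode
  out
}

#' Select the key CGSD parameters
#'
#' Picks the `k` features with the largest absolute combined score `|FSC|`;
#' ties break by feature-name order so the selection is deterministic and
#' independent of input row order.
#'
#' @param scores A `key_parameter_scores` tibble from [score_coefficients()].
#' @param k Number of parameters to select (default 6).
#' @return Character vector of `k` feature names, ordered by decreasing
#'   `|FSC|`.
#' @export
select_key_parameters <- function(scores, k = 6) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    abort("k must be a positive count", class = "frostgrade_error_arg")
  }
  if (k > nrow(scores)) {
    abort("k exceeds the number of features", class = "frostgrade_error_arg")
  }
  ord <- order(-scores$abs_fsc, scores$feature)
  scores$feature[ord][seq_len(k)]
}
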