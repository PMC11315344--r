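#' Confusion matrix of predicted vs. reference severity grades
#'
#' Cross-tabulates manual (reference) grades against predicted grades; rows
#' are the reference grade, columns the prediction.
#'
#' @param reference Integer vector of reference grades in 0, 1, 2. A 3x3
#'   matrix of counts may also be given directly (with `predicted` omitted)
#'   to wrap an existing table.
#' @param predicted Integer vector of predicted grades, same length.
#' @param levels Grade levels (default `0:2`).
#' @return An object of class `confusion_matrix`: an integer `levels` x
#'   `levels` matrix with dimnames `reference`/`predicted` and attribute `n`.
#' @export
#' @examples
#' cm <- confusion_matrix(c(0, 0, 1, 2), c(0, 1, 1, 2))
#' accuracy_report(cm)
confusion_matrix <- function(reference, predicted = NULL, levels = 0:2) {
  if (is.matrix(reference) && is.null(predicted)) {
    m <- reference
    stopifnot(nrow(m) == length(levels), ncol(m) == length(levels), all(m >= 0))
  } else {
    reference <- assert_grades(reference)
    predicted <- assert_grades(predicted)
    if (length(reference) != length(predicted)) {
      abort("reference and predicted grades differ in length",
            class = "frostgrade_error_schema")
    }
    m <- table(factor(reference, levels = levels),
               factor(predicted, levels = levels))
    m <- matrix(as.integer(m), nrow = length(levels))
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(reference = as.character(levels),
                      predicted = as.character(levels))
  structure(m, class = c("confusion_matrix", "matrix", "array"),
            n = sum(m))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> reference (rows) x predicted (columns)\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Classification accuracy report
#'
#' Computes the classification accuracy as the percentage of samples whose
#' predicted grade exactly matches the agrometeorological observers'
#' assessment: overall `100 * trace / n`, and per reference grade
#' `100 * diagonal / row sum`. Grades with no reference samples are reported
#' as not applicable (`NA`).
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `accuracy_report` with elements `overall`
#'   (percent), `per_grade` (tibble: `grade`, `n`, `correct`, `accuracy`),
#'   and `n`.
#' @export
accuracy_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  n <- sum(m)
  if (n == 0) abort("empty confusion matrix", class = "frostgrade_error_empty_sample")
  row_n <- rowSums(m)
  diag_m <- diag(m)
  per <- tibble::tibble(
    grade = as.integer(rownames(m)),
    n = as.integer(row_n),
    correct = as.integer(diag_m),
    accuracy = unname(ifelse(row_n > 0, 100 * diag_m / row_n, NA_real_))
  )
  structure(list(overall = 100 * sum(diag_m) / n, per_grade = per, n = n),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> overall accuracy %.2f%% (n = %d)\n",
              x$overall, x$n))
  for (i in seq_len(nrow(x$per_grade))) {
    acc <- x$per_grade$accuracy[i]
    cat(sprintf("  grade %d (n = %3d): %s\n", x$per_grade$grade[i],
                x$per_grade$n[i],
                if (is.na(acc)) "n/a" else sprintf("%.2f%%", acc)))
  }
  invisible(x)
}

#' @describeIn accuracy_report Per-grade accuracies as a tibble.
#' @param x An `accuracy_report`.
#' @param ... Unused.
#' @export
tidy.accuracy_report <- function(x, ...) x$per_grade

#' @describeIn accuracy_report One-row overall summary.
#' @export
glance.accuracy_report <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall, n = x$n)
}

#' Feature correlations with severity grade
#'
#' Pearson (default) or Spearman correlation of every feature with the
#' severity grade treated as numeric 0/1/2, with two-sided p-values and the
#' conventional significance stars. Zero-variance features are reported with
#' an undefined (`NA`) coefficient and flagged rather than forced to 0.
#'
#' @param data A data frame with a `grade` column and feature columns.
#' @param features Optional character vector naming the feature columns.
#' @param grade_col Name of the grade column (default `"grade"`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A tibble with columns `feature`, `r`, `p_value`, `stars`
#'   (`"**"` p < 0.01, `"*"` p < 0.05), `undefined`.
#' @export
correlate_with_severity <- function(data, features = NULL, grade_col = "grade",
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  grade <- assert_grades(data[[grade_col]])
  if (length(grade) < 3) {
    abort("need at least 3 samples to correlate", class = "frostgrade_error_schema")
  }
  x <- feature_matrix(data, features)
  purrr::map_dfr(colnames(x), function(f) {
    v <- x[, f]
    if (sd(v) == 0 || sd(grade) == 0) {
      return(tibble::tibble(feature = f, r = NA_real_, p_value = NA_real_,
                            stars = NA_character_, undefined = TRUE))
    }
    ct <- suppressWarnings(cor.test(v, grade, method = method, exact = FALSE))
    tibble::tibble(
      feature = f, r = unname(ct$estimate), p_value = ct$p.value,
      stars = if (ct$p.value < 0.01) "**" else if (ct$p.value < 0.05) "*" else "",
      undefined = FALSE
    )
  })
}

#' Write evaluation tables to CSV and JSON
#'
#' Mirrors the layout of the printed report tables: a confusion matrix with
#' per-grade and overall accuracies, written both as CSV and JSON.
#'
#' @param cm A [confusion_matrix()].
#' @param path_base Output path without extension; `.csv` and `.json` files
#'   are written.
#' @return The two paths, invisibly.
#' @export
write_accuracy_report <- function(cm, path_base) {
  rep <- accuracy_report(cm)
  df <- tibble::as_tibble(as.data.frame.matrix(unclass(cm)))
  names(df) <- paste0("pred_", colnames(cm))
  df <- dplyr::bind_cols(tibble::tibble(reference = rownames(cm)), df)
  df$accuracy <- ifelse(is.na(rep$per_grade$accuracy), "n/a",
                        sprintf("%.2f%%", rep$per_grade$accuracy))
  csv <- paste0(path_base, ".csv"); js <- paste0(path_base, ".json")
  readr::write_csv(df, csv)
  jsonlite::write_json(
    list(counts = unclass(cm), overall_accuracy = rep$overall,
         per_grade = rep$per_grade, n = rep$n),
    js, digits = NA, matrix = "rowmajor"
  )
  invisible(c(csv, js))
}
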