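#' Fit a Gaussian naive Bayes severity classifier
#'
#' Trains the supervised grading model: class priors are the training
#' frequencies of the manually assessed severity grades (the prior data), and
#' each feature gets a per-class Gaussian with the class mean and population
#' variance. A smoothing floor of `var_smoothing` times the largest overall
#' feature variance is added to every variance so constant features stay
#' usable.
#'
#' @param data A data frame with a `grade` column (values in 0, 1, 2) and
#'   feature columns.
#' @param features Optional character vector naming the feature columns.
#' @param grade_col Name of the grade column (default `"grade"`).
#' @param var_smoothing Smoothing fraction (default `1e-9`).
#' @return An object of class `naive_bayes_model`.
#' @export
#' @examples
#' train <- data.frame(grade = rep(0:1, each = 5),
#'                     x = c(rnorm(5, 0), rnorm(5, 100)))
#' fit <- fit_naive_bayes(train)
#' predict_naive_bayes(fit, data.frame(x = c(-1, 99)))
fit_naive_bayes <- function(data, features = NULL, grade_col = "grade",
                            var_smoothing = 1e-9) {
  if (!grade_col %in% names(data)) {
    abort(paste0("missing grade column '", grade_col, "'"),
          class = "frostgrade_error_config")
  }
  grade <- assert_grades(data[[grade_col]])
  x <- feature_matrix(data, features)
  classes <- sort(unique(grade))
  if (length(classes) < 1) abort("no training samples", class = "frostgrade_error_schema")
  pop_var <- function(v) mean((v - mean(v))^2)
  means <- do.call(rbind, lapply(classes, function(k) {
    colMeans(x[grade == k, , drop = FALSE])
  }))
  vars <- do.call(rbind, lapply(classes, function(k) {
    apply(x[grade == k, , drop = FALSE], 2, pop_var)
  }))
  epsilon <- var_smoothing * max(apply(x, 2, pop_var))
  vars <- vars + epsilon
  if (any(vars <= 0)) {
    # all features constant overall: fall back to an absolute floor
    vars <- vars + 1e-12
  }
  priors <- as.numeric(table(factor(grade, levels = classes))) / length(grade)
  dimnames(means) <- dimnames(vars) <- list(paste0("grade_", classes), colnames(x))
  structure(
    list(classes = classes, priors = priors, means = means, vars = vars,
         epsilon = epsilon, features = colnames(x)),
    class = "naive_bayes_model"
  )
}

#' @export
print.naive_bayes_model <- function(x, ...) {
  cat(sprintf("<naive_bayes_model> %d class(es), %d feature(s)\n",
              length(x$classes), length(x$features)))
  cat("  priors:", paste(sprintf("%d: %.3f", x$classes, x$priors), collapse = ", "), "\n")
  invisible(x)
}

#' Grade new samples with a fitted naive Bayes model
#'
#' Computes class posteriors by Bayes' rule over the per-feature Gaussian
#' densities (via log-sum-exp) and assigns the maximum-posterior grade, ties
#' broken toward the lower grade.
#'
#' @param model A [fit_naive_bayes()] model.
#' @param data A data frame containing the model's feature columns.
#' @return A tibble with `.pred_grade` and one posterior column per class
#'   (`.post_0`, `.post_1`, ...); posteriors sum to 1 per sample.
#' @export
predict_naive_bayes <- function(model, data) {
  stopifnot(inherits(model, "naive_bayes_model"))
  missing <- setdiff(model$features, names(data))
  if (length(missing) > 0) {
    abort(paste0("prediction table lacks feature(s): ",
                 paste(missing, collapse = ", ")),
          class = "frostgrade_error_schema")
  }
  x <- feature_matrix(data, model$features)
  loglik <- vapply(seq_along(model$classes), function(ki) {
    mu <- model$means[ki, ]; v <- model$vars[ki, ]
    rowSums(-0.5 * (log(2 * pi * matrix(v, nrow(x), ncol(x), byrow = TRUE)) +
                      sweep(x, 2, mu)^2 / matrix(v, nrow(x), ncol(x), byrow = TRUE))) +
      log(model$priors[ki])
  }, numeric(nrow(x)))
  loglik <- matrix(loglik, nrow = nrow(x))
  mx <- apply(loglik, 1, max)
  post <- exp(loglik - mx)
  post <- post / rowSums(post)
  # ties toward the lower grade: which.max returns the first maximum and
  # classes are sorted ascending
  pred <- model$classes[apply(post, 1, which.max)]
  out <- tibble::tibble(.pred_grade = as.integer(pred))
  post_df <- tibble::as_tibble(post, .name_repair = ~ paste0(".post_", model$classes))
  dplyr::bind_cols(out, post_df)
}

#' @describeIn fit_naive_bayes Tidy the per-class Gaussian parameters into a
#'   tibble with columns `grade`, `feature`, `mean`, `variance`, `prior`.
#' @param x A `naive_bayes_model`.
#' @param ... Unused.
#' @export
tidy.naive_bayes_model <- function(x, ...) {
  # means/vars are classes x features; column-major flattening pairs with
  # grade varying fastest
  tibble::tibble(
    grade = rep(x$classes, times = length(x$features)),
    feature = rep(x$features, each = length(x$classes)),
    mean = as.vector(x$means),
    variance = as.vector(x$vars),
    prior = rep(x$priors, times = length(x$features))
  )
}

#' @describeIn fit_naive_bayes One-row model summary.
#' @export
glance.naive_bayes_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes),
                 n_features = length(x$features),
                 epsilon = x$epsilon)
}

#' Serialize a naive Bayes model to JSON
#'
#' @param model A `naive_bayes_model`.
#' @param path Output path.
#' @return `path` invisibly (`write_naive_bayes`); a `naive_bayes_model`
#'   (`read_naive_bayes`).
#' @export
write_naive_bayes <- function(model, path) {
  stopifnot(inherits(model, "naive_bayes_model"))
  jsonlite::write_json(
    list(classes = model$classes, priors = model$priors,
         means = model$means, vars = model$vars,
         epsilon = model$epsilon, features = model$features),
    path, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_naive_bayes
#' @export
read_naive_bayes <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- matrix(obj$means, nrow = length(obj$classes), byrow = FALSE)
  vars <- matrix(obj$vars, nrow = length(obj$classes), byrow = FALSE)
  dimnames(means) <- dimnames(vars) <-
    list(paste0("grade_", obj$classes), obj$features)
  structure(
    list(classes = as.integer(obj$classes), priors = obj$priors,
         means = means, vars = vars, epsilon = obj$epsilon,
         features = obj$features),
    class = "naive_bayes_model"
  )
}
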