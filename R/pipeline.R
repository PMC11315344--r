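# Table-3 style model registry: which feature source each model id accepts
.model_sources <- c(F1 = "met", F2 = "cgsd", F3 = "met", F4 = "cgsd",
                    F5 = "cgsd", F5_Optimized = "cgsd")

#' Configuration for an end-to-end grading run
#'
#' Binds together a model id, its feature source, the dataset to run on, and
#' the seeds and counts that make the run reproducible. Model/feature-source
#' pairings are restricted to the experimental design: F1 and F3 use the 31
#' meteorological factors (hierarchical and K-means clustering), F2 and F4
#' the 20 CGSD parameters (same two algorithms), F5 the CGSD parameters with
#' naive Bayes, and F5_Optimized naive Bayes on the `k` key parameters picked
#' by factor analysis.
#'
#' @param model One of `"F1"`, `"F2"`, `"F3"`, `"F4"`, `"F5"`,
#'   `"F5_Optimized"`.
#' @param feature_source `"met"` or `"cgsd"`; defaults to the model's
#'   required source and errors on a mismatch.
#' @param dataset A [dataset_config()] for synthetic image runs.
#' @param manifest Optional tibble of real images (`path`, `site`, `grade`,
#'   optional `date`); overrides synthetic generation for CGSD models.
#' @param k Number of key parameters for F5_Optimized (default 6).
#' @param met_days Length of the synthetic weather series for met models
#'   (default 90).
#' @param seed Run seed (default 20221122).
#' @param kmeans_restarts Restarts for K-means (default 10).
#' @param out_dir Optional output directory for artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(model, feature_source = NULL,
                       dataset = dataset_config(), manifest = NULL,
                       k = 6, met_days = 90, seed = 20221122,
                       kmeans_restarts = 10, out_dir = NULL) {
  if (!model %in% names(.model_sources)) {
    abort(paste0("unknown model id '", model, "'"), class = "frostgrade_error_arg")
  }
  required <- unname(.model_sources[model])
  if (is.null(feature_source)) feature_source <- required
  if (!identical(feature_source, required)) {
    abort(sprintf("model %s requires feature source '%s', not '%s'",
                  model, required, feature_source),
          class = "frostgrade_error_arg")
  }
  structure(list(model = model, feature_source = feature_source,
                 dataset = dataset, manifest = manifest, k = k,
                 met_days = met_days, seed = seed,
                 kmeans_restarts = kmeans_restarts, out_dir = out_dir),
            class = "run_config")
}

#' Run one grading model end-to-end
#'
#' Executes the full pipeline for the configured model: data generation or
#' manifest loading, feature extraction, optional key-parameter selection,
#' model fitting or clustering, cluster-to-grade mapping (unsupervised models
#' only), and accuracy evaluation per split. The modeling split is exactly
#' the upper-left quadrants of modeling-site images; validation and testing
#' samples never enter training. Artifacts (features, model, predictions,
#' reports) are written under `config$out_dir` when given.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log messages (default `FALSE`).
#' @return A list of class `frostgrade_run`: the config, the feature table,
#'   per-split confusion matrices and accuracy reports, predictions, and for
#'   F5_Optimized the selected key parameters.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config("F5_Optimized",
#'                   dataset = dataset_config(width = 64, height = 64))
#' run <- run_model(cfg, quiet = TRUE)
#' run$reports$validation
#' }
run_model <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  model_id <- config$model
  say("[%s] starting run (seed %d)", model_id, config$seed)

  if (config$feature_source == "met") {
    daily <- generate_met_series(n_days = config$met_days, seed = config$seed)
    factors <- derive_met_factors(daily)
    table <- dplyr::filter(factors, .data$complete)
    say("[%s] met series: %d days, %d complete factor rows",
        model_id, nrow(daily), nrow(table))
    features <- paste0("Z", 1:31)
    result <- run_unsupervised(config, table, features, say)
  } else {
    if (is.null(config$manifest)) {
      ds <- generate_labeled_dataset(config$dataset, seed = config$seed)
      table <- ds$samples
    } else {
      table <- load_manifest(config$manifest)
    }
    say("[%s] samples: %s", model_id,
        paste(names(table(table$role)), table(table$role),
              sep = " = ", collapse = ", "))
    features <- cgsd_parameter_names()
    result <- switch(model_id,
      F2 = ,
      F4 = run_unsupervised(config,
                            dplyr::filter(table, .data$role == "modeling"),
                            features, say),
      F5 = run_bayes(config, table, features, say),
      F5_Optimized = run_bayes_optimized(config, table, features, say)
    )
    result$samples <- table
  }
  result$config <- config
  result$model <- model_id
  class(result) <- "frostgrade_run"
  if (!is.null(config$out_dir)) write_run_artifacts(result, config$out_dir)
  result
}

run_unsupervised <- function(config, table, features, say) {
  algo <- if (config$model %in% c("F1", "F2")) "hierarchical" else "kmeans"
  assignment <- if (algo == "hierarchical") {
    hierarchical_cluster(table, k = 3, features = features)
  } else {
    kmeans_cluster(table, k = 3, features = features, seed = config$seed,
                   restarts = config$kmeans_restarts)
  }
  mapped <- map_clusters_to_grades(assignment, table$grade)
  cm <- confusion_matrix(table$grade, mapped$mapped_grade)
  rep <- accuracy_report(cm)
  say("[%s] %s clustering: %d/%d samples matched (%.2f%%)", config$model,
      algo, attr(mapped, "agreement"), nrow(table), rep$overall)
  list(assignment = mapped,
       confusion = list(modeling = cm),
       reports = list(modeling = rep))
}

run_bayes <- function(config, table, features, say) {
  splits <- split(table, table$role)
  if (is.null(splits$modeling) || !"grade" %in% names(table) ||
      anyNA(splits$modeling$grade)) {
    abort("naive Bayes training needs labeled modeling samples",
          class = "frostgrade_error_config")
  }
  fit <- fit_naive_bayes(splits$modeling, features = features)
  say("[%s] trained on %d modeling samples, %d features", config$model,
      nrow(splits$modeling), length(features))
  confusion <- list(); reports <- list(); predictions <- list()
  for (split_name in intersect(c("modeling", "validation", "testing"),
                               names(splits))) {
    part <- splits[[split_name]]
    pred <- predict_naive_bayes(fit, part)
    cm <- confusion_matrix(part$grade, pred$.pred_grade)
    confusion[[split_name]] <- cm
    reports[[split_name]] <- accuracy_report(cm)
    predictions[[split_name]] <- dplyr::bind_cols(
      part[intersect(c("sample_id", "site", "quadrant", "grade"), names(part))],
      pred)
    say("[%s] %s accuracy: %.2f%% (n = %d)", config$model, split_name,
        reports[[split_name]]$overall, nrow(part))
  }
  list(fit = fit, features_used = features, confusion = confusion,
       reports = reports, predictions = predictions)
}

run_bayes_optimized <- function(config, table, features, say) {
  modeling <- dplyr::filter(table, .data$role == "modeling")
  screening <- withCallingHandlers({
    km <- kmo(modeling, features = features)
    bt <- bartlett_sphericity(modeling, features = features)
    list(kmo = km, bartlett = bt)
  }, warning = function(w) invokeRestart("muffleWarning"))
  say("[%s] screening: KMO %.3f, Bartlett p %.3g", config$model,
      screening$kmo$kmo, screening$bartlett$p_value)
  fm <- suppressWarnings(extract_factors(modeling, features = features,
                                         screen = FALSE))
  scores <- score_coefficients(fm)
  keys <- select_key_parameters(scores, k = config$k)
  say("[%s] selected key parameters: %s", config$model,
      paste(keys, collapse = ", "))
  out <- run_bayes(config, table, keys, say)
  out$screening <- screening
  out$factor_model <- fm
  out$scores <- scores
  out$key_parameters <- keys
  out
}

load_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest), all(c("path", "grade") %in% names(manifest)))
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    img <- read_canopy_image(manifest$path[i])
    quads <- split_quadrants(img)
    purrr::map_dfr(names(quads), function(qn) {
      id <- paste0(tools::file_path_sans_ext(basename(manifest$path[i])), "_", qn)
      dplyr::bind_cols(
        tibble::tibble(
          site = manifest$site[i] %||% NA_character_,
          image_id = manifest$path[i], quadrant = qn,
          role = attr(quads[[qn]], "role")),
        extract_cgsd(quads[[qn]], sample_id = id, grade = manifest$grade[i])
      )
    })
  })
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$samples)) {
    write_cgsd_table(run$samples, file.path(out_dir, "features.csv"))
  }
  if (!is.null(run$fit)) {
    write_naive_bayes(run$fit, file.path(out_dir, "model.json"))
  }
  for (split_name in names(run$confusion)) {
    write_accuracy_report(run$confusion[[split_name]],
                          file.path(out_dir, paste0("confusion_", split_name)))
  }
  for (split_name in names(run$predictions)) {
    readr::write_csv(run$predictions[[split_name]],
                     file.path(out_dir, paste0("predictions_", split_name, ".csv")))
  }
  if (!is.null(run$scores)) {
    readr::write_csv(tibble::as_tibble(run$scores),
                     file.path(out_dir, "score_coefficients.csv"))
  }
  invisible(out_dir)
}

#' @export
print.frostgrade_run <- function(x, ...) {
  cat(sprintf("<frostgrade_run> model %s\n", x$model))
  for (split_name in names(x$reports)) {
    cat(sprintf("  %s: overall %.2f%% (n = %d)\n", split_name,
                x$reports[[split_name]]$overall, x$reports[[split_name]]$n))
  }
  if (!is.null(x$key_parameters)) {
    cat("  key parameters:", paste(x$key_parameters, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn run_model One row per split with overall accuracy.
#' @param x A `frostgrade_run`.
#' @param ... Unused.
#' @export
glance.frostgrade_run <- function(x, ...) {
  purrr::map_dfr(names(x$reports), function(s) {
    tibble::tibble(model = x$model, split = s,
                   overall_accuracy = x$reports[[s]]$overall,
                   n = x$reports[[s]]$n)
  })
}
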