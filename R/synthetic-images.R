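#' Severity-dependent canopy color model
#'
#' Defines the pixel-level color mixture used by the synthetic canopy-image
#' generator. Pixels are drawn from three populations -- healthy green,
#' yellow-green and yellow leaf color -- whose mixture weights depend on the
#' severity grade: an uninjured canopy is dominated by concentrated bright
#' green, while increasing injury shifts weight toward the yellow
#' populations. This reproduces the characteristic histogram signature of
#' freeze injury: the color distribution shifts toward lighter values,
#' flattens, and skews as severity grows.
#'
#' @param populations A tibble with one row per pixel population and columns
#'   `population`, `mean_r`, `mean_g`, `mean_b`, `sd`.
#' @param weights A 3 x 3 matrix of mixture weights, rows = grades 0..2,
#'   columns = populations; each row sums to 1.
#' @return An object of class `severity_color_model`.
#' @export
severity_color_model <- function(populations = NULL, weights = NULL) {
  if (is.null(populations)) {
    populations <- tibble::tibble(
      population = c("green", "yellow_green", "yellow"),
      mean_r = c(55, 150, 205),
      mean_g = c(115, 160, 185),
      mean_b = c(45, 60, 70),
      sd = c(12, 14, 16)
    )
  }
  if (is.null(weights)) {
    # grade 0: concentrated bright green; grade 1: green-dominant with a
    # yellow shoulder; grade 2: evenly spread across all three leaf colors,
    # giving the flattest, most yellow-shifted histogram
    weights <- rbind(
      c(0.85, 0.12, 0.03),
      c(0.62, 0.28, 0.10),
      c(0.34, 0.33, 0.33)
    )
  }
  weights <- as.matrix(weights)
  dimnames(weights) <- list(grade = 0:2, population = populations$population)
  if (any(weights < 0) || any(abs(rowSums(weights) - 1) > 1e-8)) {
    abort("mixture weights must be non-negative and sum to 1 per grade",
          class = "frostgrade_error_config")
  }
  mix_r <- as.vector(weights %*% populations$mean_r)
  if (any(diff(mix_r) < -1e-8)) {
    abort("model must lighten with severity: mixture R mean must be non-decreasing in grade",
          class = "frostgrade_error_config")
  }
  structure(list(populations = populations, weights = weights),
            class = "severity_color_model")
}

#' @export
print.severity_color_model <- function(x, ...) {
  cat("<severity_color_model>\n")
  print(x$populations)
  cat("mixture weights (grade x population):\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Generate a synthetic canopy image for a severity grade
#'
#' Draws `width * height` i.i.d. pixels from the grade's color mixture:
#' a pixel population is sampled from the grade's mixture weights, then each
#' channel from a normal around the population's channel mean, rounded and
#' clamped to \[0, 255\]. Deterministic given `seed`.
#'
#' @param grade Severity grade 0, 1 or 2.
#' @param model A [severity_color_model()].
#' @param width,height Image size in pixels (defaults 256).
#' @param seed RNG seed; `NULL` uses the current RNG state (so callers can
#'   wrap a whole dataset in one seed).
#' @return A [canopy_image()].
#' @export
#' @examples
#' img <- generate_canopy_image(1, width = 64, height = 64, seed = 42)
#' extract_cgsd(img)
generate_canopy_image <- function(grade, model = severity_color_model(),
                                  width = 256, height = 256, seed = NULL) {
  grade <- assert_grades(grade)
  stopifnot(inherits(model, "severity_color_model"), width * height >= 1)
  draw <- function() {
    n <- width * height
    pop <- sample.int(nrow(model$populations), n, replace = TRUE,
                      prob = model$weights[grade + 1L, ])
    sds <- model$populations$sd[pop]
    clamp <- function(mu) {
      as.integer(pmin(pmax(round_half_up(rnorm(n, mu, sds)), 0), 255))
    }
    arr <- array(0L, dim = c(height, width, 3))
    arr[, , 1] <- clamp(model$populations$mean_r[pop])
    arr[, , 2] <- clamp(model$populations$mean_g[pop])
    arr[, , 3] <- clamp(model$populations$mean_b[pop])
    canopy_image(arr)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Dataset configuration for the synthetic observation campaign
#'
#' Describes the sample structure the generator emulates: two modeling sites
#' whose images contribute upper-left quadrants to the modeling group and the
#' remaining quadrants to the verification group, and one applied-testing
#' site whose quadrants are all used for testing. The default counts follow
#' a two-site winter observation campaign: 47 modeling-site images with grade counts 19/16/12
#' (hence 47 modeling and 141 verification quadrant samples) and 31
#' uninjured testing-site images (124 testing quadrants).
#'
#' @param modeling_counts Named integer vector: modeling-site image counts
#'   per grade `0`, `1`, `2`.
#' @param testing_counts Same, for the applied-testing site.
#' @param width,height Image size in pixels (default 256).
#' @param model A [severity_color_model()].
#' @return A list of class `dataset_config`.
#' @export
dataset_config <- function(modeling_counts = c(`0` = 19, `1` = 16, `2` = 12),
                           testing_counts = c(`0` = 31, `1` = 0, `2` = 0),
                           width = 256, height = 256,
                           model = severity_color_model()) {
  stopifnot(length(modeling_counts) == 3, length(testing_counts) == 3,
            all(modeling_counts >= 0), all(testing_counts >= 0),
            sum(modeling_counts) >= 1)
  structure(list(modeling_counts = modeling_counts,
                 testing_counts = testing_counts,
                 width = width, height = height, model = model),
            class = "dataset_config")
}

#' Generate a labeled synthetic canopy-image dataset
#'
#' Generates images per the configured per-grade counts, splits each into its
#' four quadrant samples, extracts the 20 CGSD parameters per quadrant, and
#' tags roles: modeling-site upper-left quadrants form the modeling group,
#' their remaining quadrants the validation group, and all testing-site
#' quadrants the applied-testing group. Identical config + seed reproduces
#' the dataset bit-identically.
#'
#' @param config A [dataset_config()].
#' @param seed Integer RNG seed.
#' @param keep_images Also return the raw images (default `FALSE`).
#' @return A list of class `canopy_dataset` with `samples` (a tibble:
#'   `sample_id`, `site`, `image_id`, `quadrant`, `role`, `grade`, and the 20
#'   CGSD columns) and, if requested, `images`.
#' @export
generate_labeled_dataset <- function(config = dataset_config(), seed = 20221122,
                                     keep_images = FALSE) {
  stopifnot(inherits(config, "dataset_config"))
  n_mod <- sum(config$modeling_counts)
  plan <- dplyr::bind_rows(
    # two modeling sites share the modeling-group images; a third site is
    # reserved for applied testing
    tibble::tibble(site = rep_len(c("site_a", "site_b"), n_mod),
                   grade = rep(0:2, times = config$modeling_counts)),
    tibble::tibble(site = "site_c",
                   grade = rep(0:2, times = config$testing_counts))
  )
  plan$image_id <- sprintf("%s_img%03d", plan$site, seq_len(nrow(plan)))
  images <- list()
  samples <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(plan)), function(i) {
      img <- generate_canopy_image(plan$grade[i], model = config$model,
                                   width = config$width, height = config$height,
                                   seed = NULL)
      if (keep_images) images[[plan$image_id[i]]] <<- img
      quads <- split_quadrants(img)
      purrr::map_dfr(names(quads), function(qn) {
        role <- if (plan$site[i] == "site_c") "testing" else attr(quads[[qn]], "role")
        feats <- extract_cgsd(quads[[qn]],
                              sample_id = paste(plan$image_id[i], qn, sep = "_"),
                              grade = plan$grade[i])
        dplyr::bind_cols(
          tibble::tibble(site = plan$site[i], image_id = plan$image_id[i],
                         quadrant = qn, role = role),
          feats
        )
      })
    })
  })
  samples <- dplyr::relocate(samples, "sample_id", "site", "image_id",
                             "quadrant", "role", "grade")
  out <- list(samples = samples, config = config, seed = seed)
  if (keep_images) out$images <- images
  structure(out, class = "canopy_dataset")
}

#' @export
print.canopy_dataset <- function(x, ...) {
  counts <- table(x$samples$role)
  cat(sprintf("<canopy_dataset> %d quadrant samples (%s)\n",
              nrow(x$samples),
              paste(names(counts), counts, sep = ": ", collapse = ", ")))
  invisible(x)
}
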