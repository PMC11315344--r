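standardize_features <- function(x) {
  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1 # constant features contribute nothing either way
  scale(x, center = TRUE, scale = sds)
}

#' K-means clustering of a feature table
#'
#' Lloyd's algorithm with k-means++ style seeding, run `restarts` times from
#' the given seed and keeping the solution with the lowest within-cluster sum
#' of squares. Features are z-score standardized by default (color and
#' meteorological features live on very different scales). An emptied cluster
#' is re-seeded from the point farthest from its centroid.
#'
#' @param data A data frame of samples by features.
#' @param k Number of clusters.
#' @param features Optional character vector naming the feature columns.
#' @param standardize Z-score features first (default `TRUE`).
#' @param seed RNG seed for seeding/restarts (default 20221122).
#' @param restarts Number of independent starts (default 10).
#' @param max_iter Lloyd iteration cap per start (default 100).
#' @return A tibble of class `cluster_assignment` with columns `sample_id`
#'   (if present in `data`) and `cluster` (0-based), carrying attributes
#'   `k`, `method = "kmeans"` and `tot_withinss`.
#' @export
kmeans_cluster <- function(data, k, features = NULL, standardize = TRUE,
                           seed = 20221122, restarts = 10, max_iter = 100) {
  x <- feature_matrix(data, features)
  n <- nrow(x)
  if (k > n) abort("k exceeds the number of samples", class = "frostgrade_error_arg")
  if (k < 1) abort("k must be positive", class = "frostgrade_error_arg")
  if (standardize) x <- standardize_features(x)
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- lloyd_once(x, k, max_iter)
      if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
    }
  })
  assignment_tibble(data, best$cluster - 1L, k, "kmeans",
                    tot_withinss = best$tot_withinss, centers = best$centers)
}

# one k-means++ seeded Lloyd run; clusters returned 1-based
lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  # k-means++ seeding
  centers <- x[sample.int(n, 1), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- pmax(apply(point_center_dist2(x, centers), 1, min), 0)
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers <- rbind(centers, x[sample.int(n, 1, prob = probs), , drop = FALSE])
  }
  cl <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- point_center_dist2(x, centers)
    new_cl <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(new_cl == j)) {
        # re-seed an emptied cluster from the farthest point
        far <- which.max(apply(d2, 1, min))
        centers[j, ] <- x[far, ]
        new_cl[far] <- j
      }
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[new_cl == j, , drop = FALSE])
    }
    if (identical(new_cl, cl)) break
    cl <- new_cl
  }
  d2 <- point_center_dist2(x, centers)
  tot <- sum(d2[cbind(seq_len(n), cl)])
  list(cluster = cl, centers = centers, tot_withinss = tot)
}

point_center_dist2 <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
}

#' Hierarchical (systematic) clustering of a feature table
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances over
#' standardized features, cut to `k` clusters. This is the "systematic
#' clustering" baseline; it is fully deterministic.
#'
#' @inheritParams kmeans_cluster
#' @return A tibble of class `cluster_assignment` with columns `sample_id`
#'   (if present) and `cluster` (0-based), attributes `k` and
#'   `method = "hierarchical"`.
#' @export
hierarchical_cluster <- function(data, k, features = NULL, standardize = TRUE) {
  x <- feature_matrix(data, features)
  if (k > nrow(x)) abort("k exceeds the number of samples", class = "frostgrade_error_arg")
  if (standardize) x <- standardize_features(x)
  hc <- hclust(dist(x), method = "ward.D2")
  cl <- cutree(hc, k = k)
  assignment_tibble(data, as.integer(cl) - 1L, k, "hierarchical",
                    merge_heights = hc$height)
}

assignment_tibble <- function(data, cluster0, k, method, ...) {
  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(data)) data$sample_id
                else as.character(seq_len(nrow(data))),
    cluster = cluster0
  )
  class(out) <- c("cluster_assignment", class(out))
  attr(out, "k") <- k
  attr(out, "method") <- method
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' Map unsupervised clusters onto severity grades
#'
#' Unsupervised clusters carry arbitrary labels; to score them against manual
#' grades, this finds the injective cluster-to-grade assignment that
#' maximizes agreement with the reference grades, searching all permutations
#' (3! = 6 for the three severity grades).
#'
#' @param assignment A `cluster_assignment` from [kmeans_cluster()] or
#'   [hierarchical_cluster()].
#' @param reference Integer vector of reference grades (0, 1, 2), aligned
#'   with the assignment rows.
#' @param grade_levels Grades available as targets (default `0:2`).
#' @return The assignment tibble with an added `mapped_grade` column and
#'   attributes `mapping` (named vector cluster -> grade) and `agreement`.
#' @export
map_clusters_to_grades <- function(assignment, reference, grade_levels = 0:2) {
  reference <- assert_grades(reference)
  stopifnot(nrow(assignment) == length(reference))
  clusters <- sort(unique(assignment$cluster))
  if (length(clusters) > length(grade_levels)) {
    abort("more clusters than grade levels", class = "frostgrade_error_arg")
  }
  perms <- permutations(grade_levels, length(clusters))
  best_agree <- -1L
  best_map <- NULL
  for (i in seq_len(nrow(perms))) {
    map <- setNames(perms[i, ], clusters)
    agree <- sum(map[as.character(assignment$cluster)] == reference)
    if (agree > best_agree) {
      best_agree <- agree
      best_map <- map
    }
  }
  assignment$mapped_grade <- as.integer(best_map[as.character(assignment$cluster)])
  attr(assignment, "mapping") <- best_map
  attr(assignment, "agreement") <- best_agree
  assignment
}

# all ordered arrangements of r elements from v
permutations <- function(v, r = length(v)) {
  if (r == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- permutations(v[-i], r - 1)
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}
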