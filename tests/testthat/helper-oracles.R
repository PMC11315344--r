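# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's histogram code paths: statistics are
# computed directly on expanded per-pixel value vectors.

brute_stats <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  med <- {
    s <- sort(v)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  tab <- table(v)
  mode <- min(as.numeric(names(tab)[tab == max(tab)]))
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  c(mean = mu, median = med, mode = mode,
    skewness = if (m2 == 0) 0 else m3 / m2^1.5,
    kurtosis = if (m2 == 0) 0 else m4 / m2^2 - 3)
}

# all 20 CGSD values straight from the raw pixel arrays of an image
brute_cgsd <- function(image, drop_extremes = TRUE) {
  r <- as.vector(unclass(image)[, , 1])
  g <- as.vector(unclass(image)[, , 2])
  b <- as.vector(unclass(image)[, , 3])
  if (drop_extremes) {
    keep <- !((r == 255 & g == 255 & b == 255) | (r == 0 & g == 0 & b == 0))
    r <- r[keep]; g <- g[keep]; b <- b[keep]
  }
  y <- as.integer(floor(0.299 * r + 0.587 * g + 0.114 * b + 0.5))
  out <- c(brute_stats(r), brute_stats(g), brute_stats(b), brute_stats(y))
  names(out) <- cgsd_parameter_names()
  out
}

# naive Bayes posterior by direct density products (no logs)
brute_nb_posterior <- function(model, x_row) {
  num <- vapply(seq_along(model$classes), function(ki) {
    model$priors[ki] *
      prod(dnorm(x_row, model$means[ki, ], sqrt(model$vars[ki, ])))
  }, numeric(1))
  num / sum(num)
}

# exhaustive k-means optimum: enumerate all assignments of n points to k
# clusters and minimize total within-cluster squared distance to centroids
brute_kmeans_objective <- function(x, k) {
  n <- nrow(x)
  stopifnot(k^n <= 1e6)
  best <- Inf
  assign <- rep(1, n)
  repeat {
    if (length(unique(assign)) == k) {
      obj <- 0
      for (j in seq_len(k)) {
        xs <- x[assign == j, , drop = FALSE]
        ctr <- colMeans(xs)
        obj <- obj + sum(sweep(xs, 2, ctr)^2)
      }
      best <- min(best, obj)
    }
    i <- 1
    while (i <= n && assign[i] == k) { assign[i] <- 1; i <- i + 1 }
    if (i > n) break
    assign[i] <- assign[i] + 1
  }
  best
}

# naive Ward agglomeration: at each step merge the pair of clusters whose
# union minimizes the increase in total within-cluster sum of squares;
# returns the list of partitions (cluster membership vectors) after each merge
brute_ward_partitions <- function(x) {
  n <- nrow(x)
  members <- as.list(seq_len(n))
  partitions <- list()
  ess <- function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }
  while (length(members) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(members)) {
      for (b in seq_along(members)) {
        if (a >= b) next
        inc <- ess(c(members[[a]], members[[b]])) -
          ess(members[[a]]) - ess(members[[b]])
        if (inc < best[1] - 1e-12) best <- c(inc, a, b)
      }
    }
    merged <- c(members[[best[2]]], members[[best[3]]])
    members <- members[-c(best[2], best[3])]
    members[[length(members) + 1]] <- merged
    cl <- integer(n)
    for (j in seq_along(members)) cl[members[[j]]] <- j
    partitions[[length(partitions) + 1]] <- cl
  }
  partitions
}

# do two cluster labelings describe the same partition?
same_partition <- function(a, b) {
  identical(outer(a, a, `==`), outer(b, b, `==`))
}

# best agreement between clusters and grades over all label permutations
brute_best_agreement <- function(cluster, reference, grade_levels = 0:2) {
  clusters <- sort(unique(cluster))
  perms <- frostgrade:::permutations(grade_levels, length(clusters))
  best <- -1
  for (i in seq_len(nrow(perms))) {
    map <- setNames(perms[i, ], clusters)
    best <- max(best, sum(map[as.character(cluster)] == reference))
  }
  best
}

# small random feature table with named features
random_feature_table <- function(n, p, seed, names = paste0("f", seq_len(p))) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, names))
    tibble::as_tibble(x)
  })
}

# data whose sample correlation matrix is exactly R (via uncorrelated scores)
table_with_exact_correlation <- function(n, R, seed) {
  p <- ncol(R)
  withr::with_seed(seed, {
    z <- matrix(rnorm(n * p), n, p)
    z <- scale(stats::prcomp(z, center = TRUE)$x)  # exactly uncorrelated
    x <- z %*% chol(R)
    colnames(x) <- paste0("f", seq_len(p))
    tibble::as_tibble(x)
  })
}
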