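#' Filter non-informative canopy pixels
#'
#' Separates the RGB channels of a canopy image into per-pixel value lists and
#' removes pixels that carry no canopy information. By default fully saturated
#' `(255,255,255)` and fully dark `(0,0,0)` pixels are dropped; an optional
#' excess-green vegetation mask retains only pixels with `2G - R - B`
#' above a threshold.
#'
#' @param image A [canopy_image()].
#' @param drop_extremes Drop pure-white and pure-black pixels (default `TRUE`).
#' @param exg_mask Apply the excess-green index mask (default `FALSE`).
#' @param exg_threshold Retain pixels with `2G - R - B > exg_threshold`
#'   when the mask is on (default 0).
#' @return A tibble with integer columns `r`, `g`, `b`, one row per retained
#'   pixel, carrying attributes `n_total`, `n_retained` and
#'   `retained_fraction`.
#' @export
#' @examples
#' img <- generate_canopy_image(0, width = 16, height = 16, seed = 1)
#' px <- filter_canopy_pixels(img)
#' attr(px, "retained_fraction")
filter_canopy_pixels <- function(image, drop_extremes = TRUE, exg_mask = FALSE,
                                 exg_threshold = 0) {
  stopifnot(inherits(image, "canopy_image"))
  r <- as.vector(unclass(image)[, , 1])
  g <- as.vector(unclass(image)[, , 2])
  b <- as.vector(unclass(image)[, , 3])
  n_total <- length(r)
  keep <- rep(TRUE, n_total)
  if (drop_extremes) {
    keep <- keep & !((r == 255 & g == 255 & b == 255) | (r == 0 & g == 0 & b == 0))
  }
  if (exg_mask) {
    keep <- keep & (2L * g - r - b > exg_threshold)
  }
  if (!any(keep)) {
    abort("no pixels retained after filtering; image is unusable",
          class = "frostgrade_error_empty_sample")
  }
  out <- tibble::tibble(r = r[keep], g = g[keep], b = b[keep])
  attr(out, "n_total") <- n_total
  attr(out, "n_retained") <- nrow(out)
  attr(out, "retained_fraction") <- nrow(out) / n_total
  out
}

#' Gray-level (luma) conversion
#'
#' Converts RGB values to an 8-bit gray level with ITU-R BT.601 weights,
#' rounded half-up and clamped to \[0, 255\].
#'
#' @param r,g,b Integer vectors of channel values in \[0, 255\].
#' @param weights Length-3 luma weights (default `c(0.299, 0.587, 0.114)`).
#' @return Integer vector of gray levels.
#' @export
#' @examples
#' gray_level(50, 150, 60) # 110
gray_level <- function(r, g, b, weights = c(0.299, 0.587, 0.114)) {
  y <- round_half_up(weights[1] * r + weights[2] * g + weights[3] * b)
  as.integer(pmin(pmax(y, 0), 255))
}

#' Per-channel color-gradation histograms
#'
#' Tabulates the 0--255 gradation histograms of the R, G and B channels and of
#' the derived gray level Y for a set of retained pixels.
#'
#' @param pixels A tibble with columns `r`, `g`, `b`
#'   (from [filter_canopy_pixels()]).
#' @param gray_weights Luma weights passed to [gray_level()].
#' @return A tibble with columns `channel` (factor R/G/B/Y), `value` (0--255)
#'   and `count`; each channel's counts sum to the pixel count.
#' @export
channel_histograms <- function(pixels, gray_weights = c(0.299, 0.587, 0.114)) {
  if (!all(c("r", "g", "b") %in% names(pixels)) || nrow(pixels) == 0) {
    abort("pixels must be a non-empty tibble with columns r, g, b",
          class = "frostgrade_error_empty_sample")
  }
  y <- gray_level(pixels$r, pixels$g, pixels$b, weights = gray_weights)
  counts <- function(v) tabulate(v + 1L, nbins = 256L)
  tibble::tibble(
    channel = factor(rep(cgsd_channels, each = 256), levels = cgsd_channels),
    value = rep(0:255, times = 4),
    count = c(counts(pixels$r), counts(pixels$g), counts(pixels$b), counts(y))
  )
}

#' Descriptive statistics of a gradation histogram
#'
#' Computes the five CGSD statistics of one channel histogram: mean, median,
#' mode, skewness and excess kurtosis. Moments are population moments about
#' the mean; skewness is `m3 / m2^(3/2)` and kurtosis `m4 / m2^2 - 3`, both
#' defined as 0 for a constant channel. The median of an even-sized sample is
#' the mean of the two middle order statistics; mode ties break toward the
#' smallest gradation value.
#'
#' @param histogram Either a tibble with columns `value` and `count` for a
#'   single channel, or a bare numeric vector of 256 counts indexed by
#'   gradation value 0--255.
#' @return A one-row tibble with columns `mean`, `median`, `mode`,
#'   `skewness`, `kurtosis`.
#' @export
#' @examples
#' histogram_statistics(tibble::tibble(value = c(0, 255), count = c(1, 1)))
histogram_statistics <- function(histogram) {
  if (is.data.frame(histogram)) {
    if (length(unique(histogram[["channel"]] %||% "x")) > 1) {
      abort("histogram_statistics expects a single channel",
            class = "frostgrade_error_schema")
    }
    counts <- numeric(256)
    counts[histogram$value + 1L] <- histogram$count
  } else {
    counts <- as.numeric(histogram)
    if (length(counts) != 256) {
      abort("histogram must have 256 bins", class = "frostgrade_error_schema")
    }
  }
  n <- sum(counts)
  if (n <= 0) abort("empty histogram", class = "frostgrade_error_empty_sample")
  v <- 0:255
  mu <- sum(v * counts) / n

  cum <- cumsum(counts)
  if (n %% 2 == 1) {
    med <- v[which(cum >= (n + 1) / 2)[1]]
  } else {
    lo <- v[which(cum >= n / 2)[1]]
    hi <- v[which(cum >= n / 2 + 1)[1]]
    med <- (lo + hi) / 2
  }
  mode <- v[which.max(counts)] # which.max takes the first (smallest) on ties

  d <- v - mu
  m2 <- sum(d^2 * counts) / n
  if (m2 == 0) {
    skew <- 0; kurt <- 0
  } else {
    m3 <- sum(d^3 * counts) / n
    m4 <- sum(d^4 * counts) / n
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2 - 3
  }
  tibble::tibble(mean = mu, median = med, mode = mode,
                 skewness = skew, kurtosis = kurt)
}

#' Extract the 20 CGSD parameters of a canopy image
#'
#' Runs the full feature pipeline on one image sample: pixel filtering,
#' R/G/B/Y gradation histograms, and the five descriptive statistics per
#' channel.
#'
#' @inheritParams filter_canopy_pixels
#' @param sample_id Optional sample identifier carried into the output.
#' @param grade Optional severity grade (0, 1, 2) carried into the output.
#' @param gray_weights Luma weights passed to [gray_level()].
#' @return A one-row tibble with `sample_id`, `grade` and the 20 named CGSD
#'   columns in [cgsd_parameter_names()] order.
#' @export
#' @examples
#' img <- generate_canopy_image(2, width = 32, height = 32, seed = 7)
#' extract_cgsd(img, sample_id = "demo", grade = 2)
extract_cgsd <- function(image, sample_id = NA_character_, grade = NA_integer_,
                         drop_extremes = TRUE, exg_mask = FALSE,
                         exg_threshold = 0,
                         gray_weights = c(0.299, 0.587, 0.114)) {
  px <- filter_canopy_pixels(image, drop_extremes = drop_extremes,
                             exg_mask = exg_mask, exg_threshold = exg_threshold)
  hist <- channel_histograms(px, gray_weights = gray_weights)
  stats <- hist |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_modify(~ histogram_statistics(.x)) |>
    dplyr::ungroup()
  wide <- stats |>
    tidyr::pivot_longer(-"channel", names_to = "stat") |>
    dplyr::mutate(name = paste(.data$channel,
                               tools::toTitleCase(.data$stat), sep = "_")) |>
    dplyr::select("name", "value") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value")
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = sample_id,
                   grade = if (is.na(grade)) NA_integer_ else assert_grades(grade)),
    wide[cgsd_parameter_names()]
  )
  attr(out, "retained_fraction") <- attr(px, "retained_fraction")
  out
}

#' Write a CGSD feature table to CSV
#'
#' Writes one row per sample with identifier/metadata columns first, the 20
#' CGSD parameters in canonical order, and the severity grade last.
#'
#' @param data A tibble containing the 20 CGSD columns, plus any of
#'   `sample_id`, `site`, `date`, `quadrant`, `role`, `grade`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cgsd_table <- function(data, path) {
  missing <- setdiff(cgsd_parameter_names(), names(data))
  if (length(missing) > 0) {
    abort(paste0("missing CGSD column(s): ", paste(missing, collapse = ", ")),
          class = "frostgrade_error_schema")
  }
  meta <- intersect(c("sample_id", "site", "date", "quadrant", "role"), names(data))
  cols <- c(meta, cgsd_parameter_names(), intersect("grade", names(data)))
  readr::write_csv(data[cols], path)
  invisible(path)
}
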