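#' Generate a synthetic daily agrometeorological series
#'
#' Simulates the daily weather record of one winter site: air temperature
#' declining along a seasonal trend with autocorrelated noise, in-field
#' temperatures at 30/60/150 cm, minimum, dew-point and grass temperatures,
#' relative humidity and precipitation. A latent cold-exposure index (the
#' negated trailing 3-day mean of the daily minimum) is thresholded at its
#' terciles to assign a daily freeze-injury severity grade, so colder periods
#' carry higher grades and severity correlates negatively with the
#' temperature factors.
#'
#' @param n_days Series length (at least 7, default 90).
#' @param start First date (default `"2022-11-10"`).
#' @param t_start,t_end Mean air temperature at the start and end of the
#'   series, degrees C (defaults 8 and -6).
#' @param noise_sd Daily noise standard deviation (default 1.5).
#' @param seed Integer RNG seed.
#' @return A tibble with one row per day: `date`, `t_mean`, `t_min`,
#'   `t_30cm`, `t_60cm`, `t_150cm`, `t_dew`, `t_grass`, `rh`, `precip`,
#'   `grade`.
#' @export
generate_met_series <- function(n_days = 90, start = as.Date("2022-11-10"),
                                t_start = 8, t_end = -6, noise_sd = 1.5,
                                seed = 20221122) {
  if (n_days < 7) {
    abort("need at least 7 days so the 5-day moving windows exist",
          class = "frostgrade_error_arg")
  }
  withr::with_seed(seed, {
    trend <- seq(t_start, t_end, length.out = n_days)
    ar <- as.numeric(stats::filter(rnorm(n_days, 0, noise_sd), 0.6,
                                   method = "recursive"))
    t_mean <- trend + ar
    t_min <- t_mean - runif(n_days, 3, 6)
    daily <- tibble::tibble(
      date = start + seq_len(n_days) - 1,
      t_mean = t_mean,
      t_min = t_min,
      t_30cm = t_mean + 0.8 + rnorm(n_days, 0, 0.4),
      t_60cm = t_mean + 0.4 + rnorm(n_days, 0, 0.4),
      t_150cm = t_mean + rnorm(n_days, 0, 0.4),
      t_dew = t_mean - runif(n_days, 1, 4),
      t_grass = t_min - 1 + rnorm(n_days, 0, 0.6),
      rh = pmin(pmax(70 + 0.8 * ar + rnorm(n_days, 0, 6), 20), 100),
      precip = ifelse(runif(n_days) < 0.15, round(stats::rexp(n_days, 1 / 3), 1), 0)
    )
    chill <- -zoo::rollmeanr(daily$t_min, 3, fill = NA)
    chill[is.na(chill)] <- chill[3]
    if (sd(chill) == 0) {
      daily$grade <- 0L
    } else {
      cuts <- stats::quantile(chill, c(1 / 3, 2 / 3))
      daily$grade <- as.integer(findInterval(chill, cuts, left.open = TRUE))
    }
    daily
  })
}

#' Derive the 31 meteorological factors from a daily series
#'
#' Computes the factor table used by the meteorological classification
#' baselines: Z1, the effective accumulated temperature since sowing (running
#' sum of daily mean temperature above `base_temp`); the daily factors
#' Z2/Z5/Z8/Z11/Z14/Z20/Z23/Z26/Z29; their trailing 3-day (Z3, Z6, Z9, Z12,
#' Z15, Z21, Z24, Z27, Z30) and 5-day (Z4, Z7, Z10, Z13, Z16, Z22, Z25, Z28,
#' Z31) moving means; and the 24-hour temperature change Z17 with its moving
#' means Z18/Z19. Moving windows are trailing. Rows whose largest window is
#' not yet available are flagged `complete = FALSE` and should be excluded
#' from modeling tables.
#'
#' @param daily A daily series from [generate_met_series()] (or any tibble
#'   with the same columns).
#' @param base_temp Base temperature for Z1, degrees C (default 0).
#' @return A tibble with `date`, `grade` (if present), `Z1` ... `Z31`, and
#'   `complete`.
#' @export
#' @examples
#' daily <- generate_met_series(n_days = 30, seed = 1)
#' derive_met_factors(daily)
derive_met_factors <- function(daily, base_temp = 0) {
  needed <- c("t_mean", "t_min", "t_30cm", "t_60cm", "t_150cm",
              "t_dew", "t_grass", "rh", "precip")
  missing <- setdiff(needed, names(daily))
  if (length(missing) > 0) {
    abort(paste0("daily series lacks column(s): ", paste(missing, collapse = ", ")),
          class = "frostgrade_error_schema")
  }
  if (nrow(daily) < 7) {
    abort("need at least 7 days so the 5-day moving windows exist",
          class = "frostgrade_error_arg")
  }
  roll3 <- function(x) zoo::rollmeanr(x, 3, fill = NA)
  roll5 <- function(x) zoo::rollmeanr(x, 5, fill = NA)
  z17 <- c(NA, diff(daily$t_mean))
  out <- tibble::tibble(
    date = daily$date,
    Z1 = cumsum(pmax(daily$t_mean - base_temp, 0)),
    Z2 = daily$t_mean, Z3 = roll3(daily$t_mean), Z4 = roll5(daily$t_mean),
    Z5 = daily$t_30cm, Z6 = roll3(daily$t_30cm), Z7 = roll5(daily$t_30cm),
    Z8 = daily$t_60cm, Z9 = roll3(daily$t_60cm), Z10 = roll5(daily$t_60cm),
    Z11 = daily$t_150cm, Z12 = roll3(daily$t_150cm), Z13 = roll5(daily$t_150cm),
    Z14 = daily$t_min, Z15 = roll3(daily$t_min), Z16 = roll5(daily$t_min),
    Z17 = z17, Z18 = roll3(z17), Z19 = roll5(z17),
    Z20 = daily$t_dew, Z21 = roll3(daily$t_dew), Z22 = roll5(daily$t_dew),
    Z23 = daily$t_grass, Z24 = roll3(daily$t_grass), Z25 = roll5(daily$t_grass),
    Z26 = daily$rh, Z27 = roll3(daily$rh), Z28 = roll5(daily$rh),
    Z29 = daily$precip, Z30 = roll3(daily$precip), Z31 = roll5(daily$precip)
  )
  if ("grade" %in% names(daily)) {
    out <- dplyr::mutate(out, grade = daily$grade, .after = "date")
  }
  out$complete <- stats::complete.cases(out[paste0("Z", 1:31)])
  out
}
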