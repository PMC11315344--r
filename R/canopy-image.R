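#' Construct a canopy image
#'
#' A canopy image is an 8-bit RGB raster stored as an integer array with
#' dimensions height x width x 3 and values in \[0, 255\]. An alpha channel,
#' if present, is dropped with a warning.
#'
#' @param x A numeric array with dim `c(height, width, channels)`, channels
#'   3 (RGB) or 4 (RGBA); values in \[0, 255\].
#' @return A `canopy_image` object.
#' @export
#' @examples
#' img <- canopy_image(array(rep(c(50, 150, 60), each = 4), dim = c(2, 2, 3)))
#' dim(img)
canopy_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3) {
    abort("a canopy image must be a height x width x 3 array",
          class = "frostgrade_error_dim")
  }
  if (dim(x)[3] == 4) {
    warn("alpha channel dropped from canopy image")
    x <- x[, , 1:3, drop = FALSE]
  }
  if (dim(x)[3] != 3) {
    abort("a canopy image needs exactly 3 color channels",
          class = "frostgrade_error_dim")
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 255) {
    abort("canopy image values must lie in [0, 255]", class = "frostgrade_error_dim")
  }
  storage.mode(x) <- "integer"
  structure(x, class = c("canopy_image", "array"))
}

#' @export
print.canopy_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<canopy_image> %d x %d pixels, 3 x 8-bit channels\n", d[2], d[1]))
  invisible(x)
}

image_width <- function(image) dim(image)[2]
image_height <- function(image) dim(image)[1]

#' Read a canopy image from a PNG or JPEG file
#'
#' Reads an 8-bit RGB image; grayscale images are replicated across the three
#' channels, and an alpha channel is dropped with a warning.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return A [canopy_image()].
#' @export
read_canopy_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    abort(paste0("unsupported image format: .", ext),
          class = "frostgrade_error_schema")
  )
  if (length(dim(raw)) == 2) raw <- array(raw, dim = c(dim(raw), 3))
  canopy_image(round_half_up(raw * 255))
}

#' Write a canopy image to a PNG file
#'
#' @param image A [canopy_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_canopy_image <- function(image, path) {
  stopifnot(inherits(image, "canopy_image"))
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

# round-half-up, unlike base round()'s round-half-even
round_half_up <- function(x) floor(x + 0.5)

#' Split a canopy image into four equal quadrant samples
#'
#' Divides the image into upper-left, upper-right, lower-left and lower-right
#' sections along the floor midlines. The upper-left quadrant is the modeling
#' sample; the other three are validation samples.
#'
#' @param image A [canopy_image()] with width and height at least 2.
#' @return A named list of four `canopy_image` quadrants
#'   (`upper_left`, `upper_right`, `lower_left`, `lower_right`), each carrying
#'   a `"role"` attribute (`"modeling"` for upper-left, `"validation"`
#'   otherwise).
#' @export
#' @examples
#' img <- generate_canopy_image(0, width = 8, height = 6, seed = 1)
#' lapply(split_quadrants(img), dim)
split_quadrants <- function(image) {
  stopifnot(inherits(image, "canopy_image"))
  w <- image_width(image); h <- image_height(image)
  if (w < 2 || h < 2) {
    abort("image must be at least 2 x 2 pixels to split into quadrants",
          class = "frostgrade_error_dim")
  }
  mw <- w %/% 2; mh <- h %/% 2
  take <- function(rows, cols, name, role) {
    q <- canopy_image(unclass(image)[rows, cols, , drop = FALSE])
    attr(q, "quadrant") <- name
    attr(q, "role") <- role
    q
  }
  list(
    upper_left  = take(seq_len(mh), seq_len(mw), "upper_left", "modeling"),
    upper_right = take(seq_len(mh), (mw + 1):w, "upper_right", "validation"),
    lower_left  = take((mh + 1):h, seq_len(mw), "lower_left", "validation"),
    lower_right = take((mh + 1):h, (mw + 1):w, "lower_right", "validation")
  )
}
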