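#' 2D image grid
#'
#' Container for a single 2D grayscale slice: a numeric matrix of intensities
#' plus an isotropic pixel spacing in millimetres. All registration functions
#' in the package operate on `image_grid` objects.
#'
#' Coordinate convention (used everywhere in the package): indices are
#' 0-based, `x` is the column index and `y` is the row index, with pixel
#' centers at integer coordinates. So the pixel stored at matrix position
#' `[r, c]` sits at `(x, y) = (c - 1, r - 1)`.
#'
#' @param pixels Numeric matrix of intensities (finite, any units).
#' @param pixel_spacing Millimetres per pixel (isotropic), positive scalar.
#' @return An `image_grid` object.
#' @examples
#' img <- image_grid(matrix(runif(64 * 64), 64, 64))
#' dim(img)
#' @export
image_grid <- function(pixels, pixel_spacing = 1.0) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("all intensities must be finite", call. = FALSE)
  }
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0) {
    stop("`pixel_spacing` must be a positive finite scalar", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, pixel_spacing = as.numeric(pixel_spacing)),
    class = "image_grid"
  )
}

#' @export
dim.image_grid <- function(x) dim(x$pixels)

#' Image height (rows) and width (columns) in pixels
#' @param image An `image_grid`.
#' @return Integer pixel count.
#' @export
img_height <- function(image) nrow(image$pixels)

#' @rdname img_height
#' @export
img_width <- function(image) ncol(image$pixels)

#' @export
print.image_grid <- function(x, ...) {
  rng <- range(x$pixels)
  cat(sprintf(
    "<image_grid> %d x %d px, spacing %.4g mm/px, intensity range [%.4g, %.4g]\n",
    img_height(x), img_width(x), x$pixel_spacing, rng[1], rng[2]
  ))
  invisible(x)
}

#' @exportS3Method base::all.equal
all.equal.image_grid <- function(target, current, ...) {
  all.equal(target$pixels, current$pixels, ...)
}

assert_image <- function(image, arg = "image") {
  if (!inherits(image, "image_grid")) {
    stop(sprintf("`%s` must be an image_grid", arg), call. = FALSE)
  }
  invisible(image)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels))) {
    stop("images must have the same shape", call. = FALSE)
  }
  invisible(NULL)
}
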