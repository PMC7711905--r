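#' Rigid 2D transform
#'
#' A rotation by `theta` degrees about a pivot plus a translation
#' `(tau_x, tau_y)` in pixels: `T(p) = R(theta) (p - c) + c + tau`, with the
#' pivot `c` supplied at application time (the registration pipeline always
#' rotates about the image center). Positive `theta` rotates `(1, 0)` toward
#' `(0, 1)` in the raster frame (x right, y down).
#'
#' @param theta Rotation angle in degrees; `|theta| <= 360`.
#' @param tau_x,tau_y Translation in pixels along x (columns) and y (rows).
#' @return A `rigid_transform` object.
#' @examples
#' t <- rigid_transform(theta = -2, tau_x = -4.5, tau_y = -4.5)
#' apply_to_point(t, c(200, 100), center = c(127.5, 127.5))
#' @export
rigid_transform <- function(theta = 0, tau_x = 0, tau_y = 0) {
  vals <- c(theta, tau_x, tau_y)
  if (!all(is.finite(vals))) stop("transform parameters must be finite", call. = FALSE)
  if (abs(theta) > 360) stop("|theta| must be <= 360 degrees", call. = FALSE)
  structure(
    list(theta = as.numeric(theta), tau_x = as.numeric(tau_x),
         tau_y = as.numeric(tau_y)),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> theta = %g deg, tau = (%g, %g) px\n",
              x$theta, x$tau_x, x$tau_y))
  invisible(x)
}

rotation_matrix <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
}

#' Apply a rigid transform to points
#'
#' Maps `p` to `R(theta) (p - center) + center + tau`. `p` may be a length-2
#' vector or an n-by-2 matrix of `(x, y)` coordinates (0-based pixel units).
#'
#' @param t A [rigid_transform].
#' @param p Point(s): length-2 numeric or an n x 2 matrix, columns `(x, y)`.
#' @param center Rotation pivot, length-2 `(x, y)`; defaults to the origin.
#' @return Transformed point(s), same shape as `p`.
#' @export
apply_to_point <- function(t, p, center = c(0, 0)) {
  stopifnot(inherits(t, "rigid_transform"))
  vec <- is.null(dim(p))
  pm <- if (vec) matrix(p, 1L, 2L) else as.matrix(p)
  R <- rotation_matrix(t$theta)
  out <- sweep(pm, 2L, center) %*% t(R)
  out[, 1L] <- out[, 1L] + center[1L] + t$tau_x
  out[, 2L] <- out[, 2L] + center[2L] + t$tau_y
  if (vec) as.numeric(out) else out
}

#' Invert a rigid transform
#'
#' Returns the transform `t'` with `apply_to_point(t', apply_to_point(t, p, c), c) == p`
#' for every point and pivot: rotation `-theta`, translation `-R(-theta) tau`.
#'
#' @param t A [rigid_transform].
#' @return The inverse [rigid_transform].
#' @export
inverse_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rinv <- rotation_matrix(-t$theta)
  tau <- -Rinv %*% c(t$tau_x, t$tau_y)
  rigid_transform(-t$theta, tau[1L], tau[2L])
}

#' Resample an image under a rigid transform
#'
#' Produces an image of the same shape whose content has been moved forward
#' by `t`: output pixel `x` is sampled from the input at the
#' inverse-transformed location `t^{-1}(x)` by bilinear interpolation, with
#' out-of-bounds samples set to 0. The rotation pivot is the image center
#' `((width - 1) / 2, (height - 1) / 2)`, so translation and rotation
#' parameters stay decoupled. An integer translation with `theta = 0` is an
#' exact pixel shift (no interpolation blur).
#'
#' @param moving An [image_grid] to resample.
#' @param t A [rigid_transform].
#' @return An [image_grid] of the same shape and pixel spacing.
#' @export
resample <- function(moving, t) {
  assert_image(moving, "moving")
  stopifnot(inherits(t, "rigid_transform"))
  px <- moving$pixels
  h <- nrow(px); w <- ncol(px)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  # sample locations: inverse-map every output pixel center
  Rinv <- rotation_matrix(-t$theta)
  xs <- rep(0:(w - 1), each = h) - cx - t$tau_x
  ys <- rep.int(0:(h - 1), w) - cy - t$tau_y
  sx <- Rinv[1L, 1L] * xs + Rinv[1L, 2L] * ys + cx
  sy <- Rinv[2L, 1L] * xs + Rinv[2L, 2L] * ys + cy
  out <- bilinear_sample(px, sx, sy)
  image_grid(matrix(out, h, w), moving$pixel_spacing)
}

# Bilinear sampling at (sx, sy) in 0-based (x = col, y = row) coordinates;
# zero outside the image support.
bilinear_sample <- function(px, sx, sy) {
  cpp_bilinear(px, sx, sy)
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' @param t A [rigid_transform].
#' @param path Optional file path; when `NULL`, the JSON string is returned.
#' @return `transform_to_json()`: the JSON string (invisibly when written to
#'   a file). `transform_from_json()`: a [rigid_transform].
#' @export
transform_to_json <- function(t, path = NULL) {
  stopifnot(inherits(t, "rigid_transform"))
  js <- jsonlite::toJSON(
    list(theta_deg = t$theta, tau_x_px = t$tau_x, tau_y_px = t$tau_y),
    auto_unbox = TRUE, digits = NA
  )
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' @rdname transform_to_json
#' @param json JSON string or path to a JSON file.
#' @export
transform_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  rigid_transform(x$theta_deg, x$tau_x_px, x$tau_y_px)
}
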