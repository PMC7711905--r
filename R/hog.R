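#' HOG parameters
#'
#' Parameters of the histogram-of-oriented-gradients descriptor: 8x8-pixel
#' cells whose orientation histograms are grouped into 16x16-pixel blocks
#' (2x2 cells) with a one-cell stride and L2-normalized per block. Nine
#' unsigned orientation bins over [0, 180) are the default; on a 256x256
#' image this yields (256/8 - 1)^2 blocks x 4 cells x 9 bins = 34,596
#' features.
#'
#' @param cell_size Cell side in pixels (default 8).
#' @param block_size Block side in pixels; must equal `2 * cell_size`.
#' @param block_stride Block stride in pixels; must equal `cell_size`.
#' @param n_orientations Number of orientation bins (default 9).
#' @param signed Use signed gradients over [0, 360) instead of unsigned
#'   [0, 180) (default `FALSE`).
#' @return A `hog_params` list.
#' @export
hog_params <- function(cell_size = 8L, block_size = 2L * cell_size,
                       block_stride = cell_size, n_orientations = 9L,
                       signed = FALSE) {
  cell_size <- as.integer(cell_size)
  if (cell_size < 2L) stop("`cell_size` must be >= 2", call. = FALSE)
  if (block_size != 2L * cell_size) {
    stop("`block_size` must be 2 * cell_size (2x2-cell blocks)", call. = FALSE)
  }
  if (block_stride != cell_size) {
    stop("`block_stride` must equal cell_size (one-cell stride)", call. = FALSE)
  }
  if (n_orientations < 2L) stop("`n_orientations` must be >= 2", call. = FALSE)
  structure(
    list(cell_size = cell_size, block_size = as.integer(block_size),
         block_stride = as.integer(block_stride),
         n_orientations = as.integer(n_orientations), signed = isTRUE(signed)),
    class = "hog_params"
  )
}

#' Per-pixel image gradients
#'
#' Central-difference gradients `gx = (I(x+1, y) - I(x-1, y)) / 2` (and
#' likewise `gy`), with edge replication at the borders; gradient magnitude
#' and orientation in degrees. Unsigned orientation lies in [0, 180) with 0
#' meaning a gradient along +x (e.g. across a vertical step edge).
#'
#' @param image An [image_grid], at least 3x3.
#' @param signed If `TRUE`, orientation in [0, 360); else folded to [0, 180).
#' @return List with matrices `gx`, `gy`, `magnitude`, `orientation_deg`.
#' @export
image_gradients <- function(image, signed = FALSE) {
  assert_image(image)
  px <- image$pixels
  if (nrow(px) < 3L || ncol(px) < 3L) stop("image must be at least 3x3", call. = FALSE)
  gx <- sep_filter(px, kx = c(-0.5, 0, 0.5), ky = 1)
  gy <- sep_filter(px, kx = 1, ky = c(-0.5, 0, 0.5))
  magnitude <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx) * 180 / pi
  span <- if (signed) 360 else 180
  orientation_deg <- ori %% span
  list(gx = gx, gy = gy, magnitude = magnitude, orientation_deg = orientation_deg)
}

#' Compute a HOG descriptor
#'
#' Builds per-cell orientation histograms with magnitude-weighted votes
#' split linearly between the two nearest orientation bins (circular),
#' groups 2x2 cells into blocks with a one-cell stride, L2-normalizes each
#' block (`v / sqrt(sum(v^2) + eps^2)`, eps = 1e-6) and concatenates block
#' vectors row-major over the block grid.
#'
#' Image dimensions must be divisible by the cell size; by default
#' non-divisible images are center-cropped to the largest divisible size
#' with a warning (`crop = FALSE` raises an error naming the offending
#' axis instead).
#'
#' @param image An [image_grid].
#' @param params A [hog_params] list.
#' @param crop Center-crop non-divisible images (default `TRUE`).
#' @return A `hog_descriptor`: list with `features` (numeric vector),
#'   `n_blocks_x`, `n_blocks_y`, and `params`.
#' @examples
#' img <- image_grid(matrix(runif(256 * 256), 256, 256))
#' length(compute_hog(img)$features)  # 34596
#' @export
compute_hog <- function(image, params = hog_params(), crop = TRUE) {
  assert_image(image)
  stopifnot(inherits(params, "hog_params"))
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  cs <- params$cell_size
  if (h %% cs != 0L || w %% cs != 0L) {
    if (!crop) {
      axis <- if (w %% cs != 0L) "width (x)" else "height (y)"
      stop(sprintf("image %s (%d px) is not divisible by cell_size %d",
                   axis, if (w %% cs != 0L) w else h, cs), call. = FALSE)
    }
    h2 <- (h %/% cs) * cs; w2 <- (w %/% cs) * cs
    r0 <- (h - h2) %/% 2L; c0 <- (w - w2) %/% 2L
    warning(sprintf("cropping %dx%d image to %dx%d for HOG", h, w, h2, w2),
            call. = FALSE)
    px <- px[(r0 + 1L):(r0 + h2), (c0 + 1L):(c0 + w2)]
    h <- h2; w <- w2
  }
  if (h < 2L * cs || w < 2L * cs) {
    stop("image too small for a single HOG block", call. = FALSE)
  }
  g <- image_gradients(image_grid(px, image$pixel_spacing), signed = params$signed)
  nbin <- params$n_orientations
  span <- if (params$signed) 360 else 180
  bw <- span / nbin

  ob <- g$orientation_deg / bw
  b0 <- floor(ob)
  frac <- ob - b0
  b0 <- b0 %% nbin
  b1 <- (b0 + 1) %% nbin
  w0 <- g$magnitude * (1 - frac)
  w1 <- g$magnitude * frac

  ncx <- w %/% cs; ncy <- h %/% cs
  row0 <- rep.int(0:(h - 1), w); col0 <- rep(0:(w - 1), each = h)
  cell_id <- (row0 %/% cs) * ncx + (col0 %/% cs)      # row-major cell index
  hist <- cpp_cell_hist(as.integer(cell_id),
                        as.integer(as.vector(b0)), as.integer(as.vector(b1)),
                        as.vector(w0), as.vector(w1),
                        as.integer(ncx * ncy), as.integer(nbin))

  # cells as array [bin, cx, cy]; cell_id*nbin+bin is its linear index
  A <- array(hist, c(nbin, ncx, ncy))
  nbx <- ncx - 1L; nby <- ncy - 1L
  B <- array(0, c(4L * nbin, nbx, nby))
  B[1:nbin, , ] <- A[, 1:nbx, 1:nby, drop = FALSE]                 # (cy, cx)
  B[(nbin + 1):(2 * nbin), , ] <- A[, 2:(nbx + 1), 1:nby, drop = FALSE]
  B[(2 * nbin + 1):(3 * nbin), , ] <- A[, 1:nbx, 2:(nby + 1), drop = FALSE]
  B[(3 * nbin + 1):(4 * nbin), , ] <- A[, 2:(nbx + 1), 2:(nby + 1), drop = FALSE]
  eps <- 1e-6
  norms <- sqrt(colSums(B^2) + eps^2)                 # nbx x nby
  B <- B / rep(norms, each = 4L * nbin)
  structure(
    list(features = as.vector(B), n_blocks_x = nbx, n_blocks_y = nby,
         params = params),
    class = "hog_descriptor"
  )
}

#' @export
print.hog_descriptor <- function(x, ...) {
  cat(sprintf("<hog_descriptor> %d features (%d x %d blocks, %d bins)\n",
              length(x$features), x$n_blocks_x, x$n_blocks_y,
              x$params$n_orientations))
  invisible(x)
}

#' Quantize a HOG descriptor into a probability distribution
#'
#' Block-normalized HOG features lie in [0, 1]; each feature is assigned to
#' one of `n_levels` equal-width bins over [0, 1] (values at 1 fall in the
#' top bin) and the normalized bin frequencies are returned. This is the
#' distribution whose Shannon entropy enters the HOG-based mutual
#' information.
#'
#' @param descriptor A `hog_descriptor` (or a bare numeric feature vector
#'   with values in [0, 1]).
#' @param n_levels Number of quantization levels (default 64, >= 2).
#' @return Numeric probability vector of length `n_levels`, summing to 1.
#' @export
hog_to_distribution <- function(descriptor, n_levels = 64L) {
  v <- if (inherits(descriptor, "hog_descriptor")) descriptor$features else descriptor
  if (length(v) == 0L) stop("descriptor is empty", call. = FALSE)
  if (n_levels < 2L) stop("`n_levels` must be >= 2", call. = FALSE)
  bins <- quantize_unit(v, n_levels)
  tabulate(bins, nbins = n_levels) / length(v)
}

# Equal-width quantization of values (clamped to [0,1]) into 1..n_levels.
quantize_unit <- function(v, n_levels) {
  v <- pmin(pmax(v, 0), 1)
  pmin(floor(v * n_levels), n_levels - 1L) + 1L
}
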