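#' Load a 2D image slice
#'
#' Reads a 2D grayscale slice from a NIfTI volume (`.nii`, `.nii.gz`), a PNG,
#' or a TIFF file into an [image_grid]. Intensities are cast to double and
#' otherwise left untouched: no rescaling, clipping or filtering beyond the
#' quantization inherent in the file format. Multi-channel (color) images are
#' rejected; the method is defined for scalar MRI.
#'
#' For 3D NIfTI volumes a `slice_index` (1-based, along the third axis) is
#' required; slices are extracted as stored, with no inter-slice resampling.
#' Pixel spacing is taken from the NIfTI header when present, else 1.0 mm.
#' PNG and TIFF carry no intensity-scale metadata, so values arrive on the
#' reader's native [0, 1] scale.
#'
#' @param path Path to a `.nii`, `.nii.gz`, `.png`, `.tif`/`.tiff` file.
#' @param slice_index 1-based slice index, required for 3D volumes.
#' @return An [image_grid].
#' @seealso [save_image()]
#' @export
load_image <- function(path, slice_index = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(sub("^.*?((\\.nii)?\\.[[:alnum:]]+)$", "\\1", basename(path)))
  if (ext %in% c(".nii", ".nii.gz", ".gz")) {
    vol <- RNifti::readNifti(path)
    spacing <- nifti_spacing(vol)
    arr <- as.array(vol)
    nd <- length(dim(arr))
    if (nd == 2L) {
      if (!is.null(slice_index) && slice_index != 1L) {
        stop("slice_index out of range for a 2D image", call. = FALSE)
      }
      return(image_grid(arr[, , drop = TRUE], spacing))
    }
    if (nd == 3L) {
      if (is.null(slice_index)) {
        stop("`slice_index` is required for a 3D volume", call. = FALSE)
      }
      if (slice_index < 1L || slice_index > dim(arr)[3]) {
        stop(sprintf("slice_index %d out of range [1, %d]",
                     slice_index, dim(arr)[3]), call. = FALSE)
      }
      return(image_grid(arr[, , slice_index], spacing))
    }
    stop(sprintf("unsupported NIfTI dimensionality: %dD", nd), call. = FALSE)
  }
  px <- switch(ext,
    ".png" = png::readPNG(path),
    ".tif" = ,
    ".tiff" = tiff::readTIFF(path),
    stop(sprintf("unsupported image format: %s", ext), call. = FALSE)
  )
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 1L) {
      px <- px[, , 1L]
    } else {
      stop("multi-channel images are not supported; supply a scalar image",
           call. = FALSE)
    }
  }
  image_grid(px, 1.0)
}

#' Save a 2D image slice
#'
#' Writes an [image_grid] to NIfTI (`.nii`, `.nii.gz`), PNG, or TIFF,
#' chosen by extension. NIfTI stores intensities losslessly as float and
#' records the pixel spacing, so `load_image(save_image(x))` reproduces `x`
#' exactly. PNG and TIFF are integer formats without an intensity scale:
#' intensities are mapped linearly from `[min, max]` onto the format range
#' and round-trip only up to that quantization (a constant image is written
#' as zeros).
#'
#' @param image An [image_grid].
#' @param path Output path; the parent directory must exist.
#' @param bits Bit depth for TIFF output (8 or 16); PNG is always written
#'   8-bit, NIfTI ignores this.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path, bits = 16L) {
  assert_image(image)
  if (!dir.exists(dirname(path))) {
    stop(sprintf("directory does not exist: %s", dirname(path)), call. = FALSE)
  }
  ext <- tolower(sub("^.*?((\\.nii)?\\.[[:alnum:]]+)$", "\\1", basename(path)))
  if (ext %in% c(".nii", ".nii.gz", ".gz")) {
    img <- RNifti::asNifti(image$pixels)
    img <- RNifti::`pixdim<-`(img, rep(image$pixel_spacing, 2L))
    RNifti::writeNifti(img, path, datatype = "double")
    return(invisible(path))
  }
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16", call. = FALSE)
  rng <- range(image$pixels)
  scaled <- if (rng[2] > rng[1]) {
    (image$pixels - rng[1]) / (rng[2] - rng[1])
  } else {
    matrix(0, nrow(image$pixels), ncol(image$pixels))
  }
  # snap to the format's integer lattice: the writers truncate, so values
  # must be rounded here for the error to stay within half a step
  levels <- if (ext == ".png") 255 else 2^as.integer(bits) - 1
  scaled <- round(scaled * levels) / levels
  switch(ext,
    ".png" = png::writePNG(scaled, target = path),
    ".tif" = ,
    ".tiff" = tiff::writeTIFF(scaled, where = path,
                              bits.per.sample = as.integer(bits)),
    stop(sprintf("unsupported image format: %s", ext), call. = FALSE)
  )
  invisible(path)
}

# Pixel spacing from a NIfTI header: first spatial pixdim entry when valid.
nifti_spacing <- function(vol) {
  pd <- tryCatch(RNifti::pixdim(vol), error = function(e) NULL)
  if (is.null(pd) || length(pd) < 1L || !is.finite(pd[1]) || pd[1] <= 0) {
    return(1.0)
  }
  as.numeric(pd[1])
}

#' Save a 3D stack of slices as a NIfTI volume
#'
#' Convenience writer used by the phantom CLI: stacks identically shaped
#' slices along the third axis.
#'
#' @param slices List of [image_grid] objects with identical shapes.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
save_stack <- function(slices, path) {
  stopifnot(length(slices) >= 1L)
  lapply(slices, assert_image)
  arr <- array(0, c(dim(slices[[1]]$pixels), length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$pixels
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, rep(slices[[1]]$pixel_spacing, 3L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
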