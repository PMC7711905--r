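#' Shannon entropy of a probability vector
#'
#' `H(p) = -sum(p_i log2 p_i)` with `0 * log 0 := 0`. Base-2 logarithms are
#' used throughout the package, so entropies and mutual information are in
#' bits; the base only rescales similarity traces uniformly and does not
#' move their argmax.
#'
#' @param dist Probability vector: non-negative, summing to 1 within 1e-6.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.25, 0.25))  # 1.5
#' @export
shannon_entropy <- function(dist) {
  if (any(dist < -1e-12)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(dist) - 1) > 1e-6) {
    stop("`dist` must sum to 1 (within 1e-6)", call. = FALSE)
  }
  # summing in sorted order makes the result invariant to the storage
  # order of equivalent distributions (so MI is exactly symmetric)
  p <- sort(dist[dist > 0])
  -sum(p * log2(p))
}

#' Joint distribution of two quantized value sequences
#'
#' Quantizes paired values `(a_i, b_i)` (clamped to [0, 1]) onto an
#' `n_levels` x `n_levels` grid of equal-width bins and normalizes the
#' co-occurrence counts. Rows of the joint matrix index `a`'s levels and
#' columns index `b`'s.
#'
#' @param a,b Equal-length numeric vectors with values in [0, 1].
#' @param n_levels Number of quantization levels per axis (default 64).
#' @return A `joint_distribution`: list with marginals `p` (from `a`), `q`
#'   (from `b`), joint matrix `pq`, and `n_levels`.
#' @export
joint_distribution <- function(a, b, n_levels = 64L) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length", call. = FALSE)
  if (length(a) < 1L) stop("sequences must be non-empty", call. = FALSE)
  ia <- quantize_unit(a, n_levels)
  ib <- quantize_unit(b, n_levels)
  counts <- tabulate((ib - 1L) * n_levels + ia, nbins = n_levels * n_levels)
  pq <- matrix(counts / length(a), n_levels, n_levels)
  structure(
    list(p = rowSums(pq), q = colSums(pq), pq = pq, n_levels = n_levels),
    class = "joint_distribution"
  )
}

#' Mutual information from a joint distribution
#'
#' `MI = H(p) + H(q) - H(p, q)` in bits, where `H` is the Shannon entropy
#' and `H(p, q)` the entropy of the joint matrix. Non-negative up to
#' floating-point round-off and bounded by `min(H(p), H(q))`.
#'
#' @param jd A `joint_distribution` from [joint_distribution()].
#' @return Mutual information in bits.
#' @export
mutual_information <- function(jd) {
  stopifnot(inherits(jd, "joint_distribution"))
  shannon_entropy(jd$p) + shannon_entropy(jd$q) - shannon_entropy(as.vector(jd$pq))
}

#' HOG-based mutual information between two images
#'
#' The package's core similarity measure: both images are reduced to HOG
#' descriptors with identical parameters, corresponding feature entries
#' (same descriptor index, i.e. same block, cell and orientation bin) are
#' paired, quantized, and their mutual information returned. Because the
#' features encode gradient orientation structure rather than raw
#' intensity, the measure is robust to the nonlinear intensity differences
#' between MRI modalities.
#'
#' @param source,target [image_grid]s of identical shape.
#' @param hog_params A [hog_params] list.
#' @param n_levels Quantization levels for the feature values (default 64).
#' @return Mutual information in bits.
#' @export
mi_hog <- function(source, target, hog_params = hogreg::hog_params(),
                   n_levels = 64L) {
  assert_image(source, "source"); assert_image(target, "target")
  assert_same_shape(source, target)
  fs <- compute_hog(source, hog_params)$features
  ft <- compute_hog(target, hog_params)$features
  mutual_information(joint_distribution(fs, ft, n_levels))
}

#' Intensity-based mutual information between two images
#'
#' The classical baseline: the joint histogram of co-located pixel
#' intensities, each image min-max scaled to [0, 1] before quantization
#' (necessary because the native intensity ranges of different MRI
#' modalities differ). A constant image yields a degenerate marginal and
#' MI = 0.
#'
#' @inheritParams mi_hog
#' @param n_levels Intensity quantization levels (default 64).
#' @return Mutual information in bits.
#' @export
mi_intensity <- function(source, target, n_levels = 64L) {
  assert_image(source, "source"); assert_image(target, "target")
  assert_same_shape(source, target)
  mutual_information(joint_distribution(
    minmax_unit(source$pixels), minmax_unit(target$pixels), n_levels
  ))
}

# Min-max scale to [0,1]; constant input maps to all zeros.
minmax_unit <- function(px) {
  rng <- range(px)
  if (rng[2] > rng[1]) as.vector((px - rng[1]) / (rng[2] - rng[1]))
  else numeric(length(px))
}

#' Write an MI-vs-rotation trace to CSV
#'
#' @param trace Tibble with a `theta` column and one or more MI columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mi_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
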