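#' Harris corner detection
#'
#' Detects interest points as local maxima of the Harris corner response
#' computed from the windowed second-moment matrix of image derivatives.
#' Derivatives are 3x3 Sobel; the window is a Gaussian of sigma 1.5 and
#' radius 3 px (chosen for rotational symmetry of the response). The corner
#' response from the eigenvalues `l1, l2` of the second-moment matrix is
#'
#'   `R = l1 l2 - k (l1 + l2)^2`   (standard squared-trace form, default)
#'
#' computed as `det(M) - k * trace(M)^2`. A variant without the square on the
#' trace is available via `response_form = "printed"`. Non-maximum
#' suppression over a 5x5 neighborhood isolates single points; pixels within
#' 4 px of the border (the derivative + window support) are excluded.
#'
#' @param image An [image_grid]; constant images yield zero corners.
#' @param k Harris sensitivity, conventionally 0.04-0.06 (default 0.05).
#' @param threshold Absolute response threshold on `R` in the image's native
#'   intensity units (default 1500); corners must also have `R > 0`.
#' @param max_corners Keep at most this many strongest corners (`NULL` = all).
#' @param response_form `"squared_trace"` (default) or `"printed"`
#'   (`det - k * trace`, without the square).
#' @return A `corner_set`: a tibble with columns `x`, `y` (0-based pixel
#'   coordinates) and `response`, sorted by descending response, with the
#'   detector parameters attached as attributes.
#' @examples
#' img <- image_grid(matrix(0, 64, 64))
#' img$pixels[20:40, 20:40] <- 200
#' detect_corners(img)
#' @export
detect_corners <- function(image, k = 0.05, threshold = 1500,
                           max_corners = NULL,
                           response_form = c("squared_trace", "printed")) {
  assert_image(image)
  response_form <- match.arg(response_form)
  if (k < 0.04 || k > 0.06) {
    warning("`k` outside the conventional 0.04-0.06 range", call. = FALSE)
  }
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)

  R <- harris_response(image$pixels, k = k, response_form = response_form)
  h <- nrow(R); w <- ncol(R)
  margin <- 4L
  if (h <= 2L * margin || w <= 2L * margin) {
    return(new_corner_set(numeric(0), numeric(0), numeric(0),
                          k, threshold, response_form))
  }
  # 5x5 non-maximum suppression, then threshold
  is_max <- R >= neighborhood_max(R, radius = 2L)
  keep <- is_max & R >= threshold & R > 0
  keep[c(seq_len(margin), (h - margin + 1L):h), ] <- FALSE
  keep[, c(seq_len(margin), (w - margin + 1L):w)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  resp <- R[keep]
  ord <- order(resp, decreasing = TRUE)
  x <- as.numeric(idx[ord, 2L] - 1L)
  y <- as.numeric(idx[ord, 1L] - 1L)
  resp <- resp[ord]
  if (!is.null(max_corners) && length(resp) > max_corners) {
    x <- x[seq_len(max_corners)]
    y <- y[seq_len(max_corners)]
    resp <- resp[seq_len(max_corners)]
  }
  new_corner_set(x, y, resp, k, threshold, response_form)
}

new_corner_set <- function(x, y, response, k, threshold, response_form) {
  out <- tibble::tibble(x = x, y = y, response = response)
  attr(out, "detector_params") <- list(
    k = k, threshold = threshold, response_form = response_form,
    window = "gaussian sigma 1.5 radius 3", nms = "5x5"
  )
  class(out) <- c("corner_set", class(out))
  out
}

# Harris response map over the whole image (edge-replicated filtering).
harris_response <- function(px, k, response_form) {
  gx <- sep_filter(px, kx = c(-1, 0, 1), ky = c(1, 2, 1))
  gy <- sep_filter(px, kx = c(1, 2, 1), ky = c(-1, 0, 1))
  g <- stats::dnorm(-3:3, sd = 1.5)
  g <- g / sum(g)
  Sxx <- sep_filter(gx * gx, g, g)
  Syy <- sep_filter(gy * gy, g, g)
  Sxy <- sep_filter(gx * gy, g, g)
  det_m <- Sxx * Syy - Sxy * Sxy
  tr_m <- Sxx + Syy
  if (response_form == "squared_trace") det_m - k * tr_m^2 else det_m - k * tr_m
}

# Separable filtering with edge replication: 1D kernel `kx` along columns
# (x) then `ky` along rows (y). Kernels are indexed symmetrically about 0.
sep_filter <- function(m, kx, ky) {
  cpp_sep_filter(m, as.numeric(kx), as.numeric(ky))
}

# Maximum over a (2r+1)^2 neighborhood, edge-replicated.
neighborhood_max <- function(m, radius = 2L) {
  cpp_neigh_max(m, as.integer(radius))
}

# Mutual nearest neighbors between two point sets; returns index pairs and
# distances for pairs within `gate`.
mutual_nn <- function(sx, sy, tx, ty, gate) {
  d2 <- outer(sx, tx, "-")^2 + outer(sy, ty, "-")^2
  nn_s <- max.col(-d2, ties.method = "first")
  nn_t <- max.col(-t(d2), ties.method = "first")
  si <- which(nn_t[nn_s] == seq_along(sx))
  ti <- nn_s[si]
  d <- sqrt(d2[cbind(si, ti)])
  ok <- d <= gate
  list(src = si[ok], tgt = ti[ok], distance = d[ok])
}

#' Match corners between two images
#'
#' Pairs corners by greedy mutual nearest neighbors in `(x, y)` space: a
#' source corner and a target corner are paired iff each is the other's
#' nearest neighbor and their distance is within `gate_px`. Matched corner
#' pairs serve as fiducials for the registration-error report.
#'
#' @param source,target `corner_set` tibbles (see [detect_corners()]).
#' @param max_pairs Keep at most this many closest pairs (default 30, the
#'   fiducial count used for accuracy assessment).
#' @param gate_px Reject candidate pairs farther apart than this (default 20).
#' @param warn_short Warn when fewer than `max_pairs` mutual matches exist.
#' @return A `fiducial_pairing`: tibble with columns `pair_id`, `src_x`,
#'   `src_y`, `tgt_x`, `tgt_y`, `distance`, sorted by ascending distance.
#'   Empty (zero rows) when no mutual matches fall within the gate.
#' @export
match_corners <- function(source, target, max_pairs = 30L, gate_px = 20,
                          warn_short = FALSE) {
  if (nrow(source) == 0L || nrow(target) == 0L) {
    stop("both corner sets must be non-empty", call. = FALSE)
  }
  m <- mutual_nn(source$x, source$y, target$x, target$y, gate_px)
  src_idx <- m$src; tgt_idx <- m$tgt; dist <- m$distance
  ord <- order(dist)
  src_idx <- src_idx[ord]; tgt_idx <- tgt_idx[ord]; dist <- dist[ord]
  if (length(dist) > max_pairs) {
    src_idx <- src_idx[seq_len(max_pairs)]
    tgt_idx <- tgt_idx[seq_len(max_pairs)]
    dist <- dist[seq_len(max_pairs)]
  } else if (warn_short && length(dist) < max_pairs) {
    warning(sprintf("only %d mutual corner matches (requested %d); using all",
                    length(dist), max_pairs), call. = FALSE)
  }
  out <- tibble::tibble(
    pair_id = seq_along(dist),
    src_x = source$x[src_idx], src_y = source$y[src_idx],
    tgt_x = target$x[tgt_idx], tgt_y = target$y[tgt_idx],
    distance = dist
  )
  class(out) <- c("fiducial_pairing", class(out))
  out
}

#' Mean Euclidean distance over a fiducial pairing
#'
#' The coarse-stage objective: arithmetic mean of the corner pair distances.
#'
#' @param pairing A `fiducial_pairing` from [match_corners()].
#' @return Mean distance in pixels.
#' @export
mean_pair_distance <- function(pairing) {
  if (nrow(pairing) == 0L) {
    stop("pairing is empty; mean distance is undefined", call. = FALSE)
  }
  mean(pairing$distance)
}

#' Write a corner set or pairing to CSV
#'
#' @param x A `corner_set` or `fiducial_pairing` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_corners_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
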