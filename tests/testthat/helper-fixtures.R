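# Shared fixtures and independent oracles used across test files.

# A smooth, structured image: a 2D sinusoid plus a linear ramp. Useful for
# interpolation tests because it is differentiable everywhere.
smooth_image <- function(n = 32) {
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  y <- matrix(rep(0:(n - 1), times = n), n, n)
  image_grid(50 + 30 * sin(x / 5) * cos(y / 7) + 0.3 * x + 0.1 * y)
}

# White square on black background; Harris should find its 4 vertices.
square_image <- function(n = 64, lo = 20, hi = 44, value = 200) {
  px <- matrix(0, n, n)
  px[lo:hi, lo:hi] <- value
  image_grid(px)
}

# Brute-force bilinear interpolation at a single 0-based (x, y) location;
# intentionally scalar and loop-free of any package internals.
oracle_bilinear <- function(px, x, y) {
  h <- nrow(px); w <- ncol(px)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  at <- function(xi, yi) {
    if (xi < 0 || xi > w - 1 || yi < 0 || yi > h - 1) 0 else px[yi + 1, xi + 1]
  }
  at(x0, y0) * (1 - fx) * (1 - fy) + at(x0 + 1, y0) * fx * (1 - fy) +
    at(x0, y0 + 1) * (1 - fx) * fy + at(x0 + 1, y0 + 1) * fx * fy
}

# Brute-force Shannon entropy by explicit summation.
oracle_entropy <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log2(v)
  s
}

# Build a fiducial_pairing tibble from explicit coordinates.
make_pairing <- function(src, tgt) {
  out <- tibble::tibble(
    pair_id = seq_len(nrow(src)),
    src_x = src[, 1], src_y = src[, 2],
    tgt_x = tgt[, 1], tgt_y = tgt[, 2],
    distance = sqrt((src[, 1] - tgt[, 1])^2 + (src[, 2] - tgt[, 2])^2)
  )
  class(out) <- c("fiducial_pairing", class(out))
  out
}

# Count the local maxima of a sampled trace that matter at the scale of
# the curve: strict local maxima (endpoints included) whose topographic
# prominence is at least `prominence_frac` of the trace's dynamic range.
# Without the prominence floor, float-level jitter on a flat tail would
# register as extra "peaks".
count_peaks <- function(v, prominence_frac = 0.02) {
  n <- length(v)
  rng <- diff(range(v))
  if (rng == 0) return(0L)
  peaks <- 0L
  for (i in seq_len(n)) {
    left_ok <- i == 1L || v[i] > v[i - 1]
    right_ok <- i == n || v[i] > v[i + 1]
    if (!(left_ok && right_ok)) next
    base <- -Inf
    for (side in c(-1L, 1L)) {
      j <- i
      lowest <- v[i]
      repeat {
        j <- j + side
        if (j < 1L || j > n) break
        if (v[j] > v[i]) break
        lowest <- min(lowest, v[j])
      }
      base <- max(base, lowest)
    }
    if (v[i] - base >= prominence_frac * rng) peaks <- peaks + 1L
  }
  peaks
}
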