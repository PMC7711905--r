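#' Synthetic multi-modal brain phantom pair
#'
#' Generates a fixed/moving image pair sharing one anatomy but rendered
#' under two different intensity mappings, with the moving image displaced
#' by a known rigid transform — the controlled stand-in for a T2w/DTI slice
#' pair that lets every pipeline stage be validated against ground truth.
#'
#' The anatomy is built deterministically from `seed`: an outer brain
#' ellipse with a bright cortical ribbon, two dark ventricle-like lobes,
#' and `n_structures` randomly placed sharp-edged structures (rectangles,
#' bars, blobs) that supply Harris corners and gradient texture. The
#' `"t2w-like"` modality renders the anatomy as built; `"dti-like"` applies
#' gamma compression (exponent 0.6) and inverts the contrast inside the
#' ventricle and cortical-ribbon regions, so pixelwise intensities differ
#' markedly between modalities
#' while structure is shared. The moving image is resampled by
#' `true_transform` with the same bilinear resampler used by the
#' registration, and independent Gaussian noise (`noise_sd` x the intensity
#' range) is added to both images. Identical seeds give bit-identical
#' output; the global RNG state is left untouched.
#'
#' @param size Image side in pixels, divisible by 8 (default 256).
#' @param seed Integer seed controlling anatomy, structures and noise.
#' @param modality_a,modality_b Intensity mapping for the fixed / moving
#'   image: `"t2w-like"` or `"dti-like"`.
#' @param noise_sd Additive Gaussian noise as a fraction of the intensity
#'   range (default 0.02).
#' @param true_transform The known misalignment applied to the moving
#'   image; `|theta| <= 10` degrees, `|tau| <= 8` px.
#' @param n_structures Number of random internal structures (default 12).
#' @return List with `fixed` and `moving` ([image_grid]s, intensities on a
#'   0-255 scale) and `truth` (the [rigid_transform] that was applied).
#' @examples
#' ph <- generate_phantom_pair(size = 128, seed = 7,
#'                             true_transform = rigid_transform(-2, -4.5, -4.5))
#' ph$fixed
#' @export
generate_phantom_pair <- function(size = 256L, seed = 1L,
                                  modality_a = "t2w-like",
                                  modality_b = "dti-like",
                                  noise_sd = 0.02,
                                  true_transform = rigid_transform(0, 0, 0),
                                  n_structures = 12L) {
  if (size %% 8L != 0L || size < 32L) {
    stop("`size` must be >= 32 and divisible by 8", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  stopifnot(inherits(true_transform, "rigid_transform"))
  if (abs(true_transform$theta) > 10 ||
      abs(true_transform$tau_x) > 8 || abs(true_transform$tau_y) > 8) {
    stop("true_transform must satisfy |theta| <= 10 deg, |tau| <= 8 px",
         call. = FALSE)
  }
  modality_a <- match.arg(modality_a, c("t2w-like", "dti-like"))
  modality_b <- match.arg(modality_b, c("t2w-like", "dti-like"))

  with_local_seed(seed, {
    anat <- phantom_anatomy(size, n_structures)
    fixed_px <- render_modality(anat, modality_a) * 255
    moving_px <- render_modality(anat, modality_b) * 255
    fixed <- image_grid(fixed_px)
    moving <- resample(image_grid(moving_px), true_transform)
    if (noise_sd > 0) {
      fixed$pixels <- fixed$pixels +
        matrix(stats::rnorm(size^2, sd = noise_sd * 255), size, size)
      moving$pixels <- moving$pixels +
        matrix(stats::rnorm(size^2, sd = noise_sd * 255), size, size)
    }
    list(fixed = fixed, moving = moving, truth = true_transform)
  })
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shared anatomy on [0,1] plus the ventricle mask (needed for the
# region-dependent contrast inversion of the dti-like mapping).
phantom_anatomy <- function(size, n_structures) {
  c0 <- (size - 1) / 2
  x <- matrix(rep(0:(size - 1), each = size), size, size)   # column index
  y <- matrix(rep(0:(size - 1), times = size), size, size)  # row index
  a <- 0.44 * size; b <- 0.38 * size
  e <- ((x - c0) / a)^2 + ((y - c0) / b)^2
  img <- matrix(0.02, size, size)
  img[e <= 1] <- 0.55                                  # white-matter base
  ribbon <- e >= 0.78 & e <= 1
  img[ribbon] <- 0.82                                  # cortical ribbon

  vent <- matrix(FALSE, size, size)
  for (sgn in c(-1, 1)) {
    vx <- c0 + sgn * 0.075 * size; vy <- c0 - 0.02 * size
    ang <- sgn * 20 * pi / 180
    dx <- (x - vx) * cos(ang) + (y - vy) * sin(ang)
    dy <- -(x - vx) * sin(ang) + (y - vy) * cos(ang)
    vent <- vent | ((dx / (0.05 * size))^2 + (dy / (0.13 * size))^2 <= 1)
  }
  img[vent] <- 0.12

  # random sharp-edged structures inside the brain: corner/texture sources
  for (i in seq_len(n_structures)) {
    repeat {
      sx <- stats::runif(1, 0.15, 0.85) * size
      sy <- stats::runif(1, 0.15, 0.85) * size
      if (((sx - c0) / a)^2 + ((sy - c0) / b)^2 <= 0.7) break
    }
    kind <- sample(c("rect", "bar", "blob"), 1L)
    val <- stats::runif(1, 0.25, 0.95)
    if (kind == "rect") {
      hw <- stats::runif(1, 0.015, 0.05) * size
      hh <- stats::runif(1, 0.015, 0.05) * size
      sel <- abs(x - sx) <= hw & abs(y - sy) <= hh
      img[sel] <- val
    } else if (kind == "bar") {
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, 0.05, 0.15) * size
      th <- stats::runif(1, 0.008, 0.02) * size
      dx <- (x - sx) * cos(ang) + (y - sy) * sin(ang)
      dy <- -(x - sx) * sin(ang) + (y - sy) * cos(ang)
      sel <- abs(dx) <= len & abs(dy) <= th
      img[sel] <- val
    } else {
      sg <- stats::runif(1, 0.01, 0.03) * size
      img <- img + val * 0.6 * exp(-((x - sx)^2 + (y - sy)^2) / (2 * sg^2))
    }
  }
  # band-limited parenchymal texture: brain tissue is not flat, and the
  # dense gradient-orientation structure it carries is what makes the
  # rotation similarity informative across the whole surface
  tex <- matrix(stats::rnorm(size * size), size, size)
  gt <- stats::dnorm(-3:3, sd = 1.2); gt <- gt / sum(gt)
  tex <- sep_filter(tex, gt, gt)
  tex <- tex / stats::sd(tex) * 0.12
  inside <- e <= 1
  img[inside] <- img[inside] + tex[inside]

  img <- pmin(pmax(img, 0), 1)
  # light smoothing softens aliasing without destroying corners
  g <- stats::dnorm(-2:2, sd = 0.6); g <- g / sum(g)
  img <- sep_filter(img, g, g)
  list(intensity = img, vent = vent, ribbon = ribbon)
}

render_modality <- function(anat, modality) {
  v <- anat$intensity
  if (modality == "t2w-like") return(v)
  g <- v^0.6                        # gamma compression
  inv <- anat$vent | anat$ribbon    # region-dependent contrast inversion
  g[inv] <- 1 - g[inv]
  g
}
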