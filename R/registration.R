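#' Search grid for the coarse-to-fine registration
#'
#' Exhaustive search ranges: translation from -5 to +5 px in 0.5 px steps
#' along each axis, rotation from -5 to +5 degrees in 0.5 degree steps
#' (defaults). Both endpoints are included, giving 21 values per axis.
#'
#' @param tau_min,tau_max Translation range in pixels (per axis).
#' @param tau_step Translation step in pixels.
#' @param theta_min,theta_max Rotation range in degrees.
#' @param theta_step Rotation step in degrees.
#' @return A `search_grid` list with the ranges and the realized value
#'   sequences `tau_values`, `theta_values`.
#' @export
search_grid <- function(tau_min = -5, tau_max = 5, tau_step = 0.5,
                        theta_min = -5, theta_max = 5, theta_step = 0.5) {
  if (tau_step <= 0 || theta_step <= 0) stop("steps must be > 0", call. = FALSE)
  if (tau_min >= tau_max || theta_min >= theta_max) {
    stop("min must be < max", call. = FALSE)
  }
  structure(
    list(tau_min = tau_min, tau_max = tau_max, tau_step = tau_step,
         theta_min = theta_min, theta_max = theta_max, theta_step = theta_step,
         tau_values = grid_values(tau_min, tau_max, tau_step),
         theta_values = grid_values(theta_min, theta_max, theta_step)),
    class = "search_grid"
  )
}

grid_values <- function(lo, hi, step) {
  round(seq(lo, hi, by = step), 9)
}

# Order candidate parameter values so that the first minimum/maximum found
# is the preferred one under ties: smaller |value| first, negative before
# positive.
tie_order <- function(v) order(abs(v), v)

#' Coarse translation search by corner-distance minimization
#'
#' Estimates the translation of the target relative to the source from
#' Harris corners. Corners are detected once in each image (the target
#' after undoing a hypothesized rotation `theta`, if supplied); the search
#' then works in corner space, without re-rendering the image at each
#' offset:
#'
#' 1. *Basin search*: for every candidate translation on the grid the
#'    candidate shift is subtracted from the target corners, the shifted
#'    set is matched to the source corners by mutual nearest neighbors
#'    within `match_gate`, and the candidate is scored by the summed match
#'    distances plus a `match_gate` penalty for every unmatched corner.
#'    This score is comparable across offsets (an offset cannot win by
#'    retaining only a few accidentally close pairs).
#' 2. *Paired refinement*: the correspondence found at the basin optimum
#'    is frozen, and the mean Euclidean distance (ED) between the paired
#'    corners is evaluated over the whole grid analytically. Because the
#'    same pairs are compared at every offset, corner-localization noise
#'    cancels in the comparison and the half-pixel minimum is stable.
#'
#' Ties favour the smaller-magnitude, then negative, offset in x then y.
#'
#' @param source,target [image_grid]s of identical shape.
#' @param grid A [search_grid].
#' @param theta Hypothesized rotation (degrees) undone before corner
#'   detection in the target; 0 on the first pass.
#' @param k,threshold,max_corners,response_form Harris detector settings
#'   (see [detect_corners()]).
#' @param match_gate Mutual-nearest-neighbor gate (px) for the coarse
#'   score; unmatched corners are penalized at this distance.
#' @return List with `tau` (length-2 numeric, the recovered shift of the
#'   target relative to the source), `ed_surface` (tibble `tau_x`, `tau_y`,
#'   `ed` — the paired-refinement ED), `n_pairs`, and `n_corners_source`.
#' @export
coarse_translation <- function(source, target, grid = search_grid(),
                               theta = 0, k = 0.05, threshold = 1500,
                               max_corners = 100L, match_gate = 6,
                               response_form = "squared_trace") {
  assert_image(source, "source"); assert_image(target, "target")
  assert_same_shape(source, target)
  src <- detect_corners(source, k = k, threshold = threshold,
                        max_corners = max_corners,
                        response_form = response_form)
  if (nrow(src) == 0L) {
    stop("no Harris corners in the source image; lower `threshold`",
         call. = FALSE)
  }
  corrected <- if (theta != 0) {
    resample(target, inverse_transform(rigid_transform(theta, 0, 0)))
  } else {
    target
  }
  tgt <- detect_corners(corrected, k = k, threshold = threshold,
                        max_corners = max_corners,
                        response_form = response_form)
  if (nrow(tgt) == 0L) {
    stop("no Harris corners in the target image; lower `threshold`",
         call. = FALSE)
  }

  tv <- grid$tau_values
  cand <- expand.grid(tau_x = tv, tau_y = tv, KEEP.OUT.ATTRS = FALSE)
  # after undoing rotation about the center, a model translation tau
  # displaces target content by R(-theta) tau
  a <- -theta * pi / 180
  rtx <- cos(a) * cand$tau_x - sin(a) * cand$tau_y
  rty <- sin(a) * cand$tau_x + cos(a) * cand$tau_y
  n_ref <- min(nrow(src), nrow(tgt))
  pref <- order(abs(cand$tau_x), cand$tau_x, abs(cand$tau_y), cand$tau_y)

  score <- vapply(seq_len(nrow(cand)), function(i) {
    m <- mutual_nn(src$x, src$y, tgt$x - rtx[i], tgt$y - rty[i], match_gate)
    (sum(m$distance) + (n_ref - length(m$distance)) * match_gate) / n_ref
  }, numeric(1))
  basin <- pref[which.min(score[pref])]
  m0 <- mutual_nn(src$x, src$y, tgt$x - rtx[basin], tgt$y - rty[basin],
                  match_gate)
  if (length(m0$distance) == 0L) {
    stop(paste("no corner matches at any translation offset;",
               "consider lowering `threshold` or raising `match_gate`"),
         call. = FALSE)
  }
  ux <- tgt$x[m0$tgt] - src$x[m0$src]
  uy <- tgt$y[m0$tgt] - src$y[m0$src]
  ed <- vapply(seq_len(nrow(cand)), function(i) {
    mean(sqrt((ux - rtx[i])^2 + (uy - rty[i])^2))
  }, numeric(1))
  best <- pref[which.min(ed[pref])]
  list(
    tau = c(cand$tau_x[best], cand$tau_y[best]),
    ed_surface = tibble::tibble(tau_x = cand$tau_x, tau_y = cand$tau_y,
                                ed = ed),
    n_pairs = length(m0$distance),
    n_corners_source = nrow(src)
  )
}

#' Fine rotation search by mutual-information maximization
#'
#' With the coarse translation frozen, every candidate angle on the grid is
#' scored: the hypothesized misalignment `(theta, tau)` is undone by
#' resampling the target with its inverse, and the MI between the source
#' and the corrected image is computed — from HOG feature distributions
#' (`similarity = "mi_hog"`, the package's method) or from raw intensities
#' (`"mi_intensity"`, the classical baseline). The angle maximizing MI is
#' returned; ties favour the smaller `|theta|`, then the negative angle.
#'
#' @inheritParams coarse_translation
#' @param tau Length-2 translation (px) frozen from the coarse stage.
#' @param similarity `"mi_hog"` or `"mi_intensity"`.
#' @param hog_params A [hog_params] list (mi_hog mode).
#' @param n_levels Quantization levels for the joint histogram.
#' @return List with `theta` (degrees) and `mi_trace` (tibble `theta`, `mi`
#'   in ascending `theta` order).
#' @export
fine_rotation <- function(source, target, tau = c(0, 0),
                          grid = search_grid(),
                          similarity = c("mi_hog", "mi_intensity"),
                          hog_params = hogreg::hog_params(),
                          n_levels = 64L) {
  assert_image(source, "source"); assert_image(target, "target")
  assert_same_shape(source, target)
  similarity <- match.arg(similarity)
  src_vals <- if (similarity == "mi_hog") {
    compute_hog(source, hog_params)$features
  } else {
    minmax_unit(source$pixels)
  }
  thetas <- grid$theta_values
  mi <- vapply(thetas, function(th) {
    t_cand <- rigid_transform(th, tau[1L], tau[2L])
    corrected <- resample(target, inverse_transform(t_cand))
    tgt_vals <- if (similarity == "mi_hog") {
      compute_hog(corrected, hog_params)$features
    } else {
      minmax_unit(corrected$pixels)
    }
    mutual_information(joint_distribution(src_vals, tgt_vals, n_levels))
  }, numeric(1))
  pref <- tie_order(thetas)
  best <- pref[which.max(mi[pref])]
  list(theta = thetas[best],
       mi_trace = tibble::tibble(theta = thetas, mi = mi))
}

#' Register a moving image to a fixed image
#'
#' The full coarse-to-fine rigid registration: (1) coarse translation by
#' minimizing the Euclidean distance between matched Harris corners over
#' the translation grid ([coarse_translation()]); (2) fine rotation, with
#' the translation frozen, by maximizing mutual information (HOG-based by
#' default) over the rotation grid ([fine_rotation()]). Because a large
#' uncompensated rotation displaces peripheral corners tangentially and
#' biases a translation-only corner search, the two stages are alternated:
#' after the rotation estimate the coarse stage is re-run with that
#' rotation undone, and the pair of searches repeats until the estimates
#' reproduce themselves (at most `max_iter` rounds — in practice 2 or 3).
#' Finally the recovered misalignment is undone by resampling the target
#' with the inverse transform, and the fiducial registration error is
#' computed over matched corners between the source and the registered
#' image.
#'
#' The returned `best_transform` is the estimated misalignment of the
#' target relative to the source: a target constructed by moving the source
#' with transform `t` is recovered as `t` (up to grid resolution).
#'
#' @inheritParams coarse_translation
#' @inheritParams fine_rotation
#' @param omega Number of fiducial pairs for the FRE report (default 30).
#' @param gate_px Mutual-nearest-neighbor gating radius (px) for the final
#'   fiducial pairing.
#' @param max_iter Maximum coarse/fine alternation rounds (default 4).
#' @return A `hog_registration` object; see [tidy.hog_registration()],
#'   [glance.hog_registration()], [autoplot.hog_registration()].
#' @examples
#' \donttest{
#' ph <- generate_phantom_pair(size = 128, seed = 3,
#'                             true_transform = rigid_transform(-2, -1.5, 1))
#' fit <- register(ph$fixed, ph$moving,
#'                 grid = search_grid(tau_min = -2, tau_max = 2,
#'                                    theta_min = -3, theta_max = 3))
#' glance(fit)
#' }
#' @export
register <- function(source, target, grid = search_grid(),
                     similarity = c("mi_hog", "mi_intensity"),
                     hog_params = hogreg::hog_params(), n_levels = 64L,
                     k = 0.05, threshold = 1500, max_corners = 100L,
                     match_gate = 6, gate_px = 20,
                     response_form = "squared_trace", omega = 30L,
                     max_iter = 4L) {
  assert_image(source, "source"); assert_image(target, "target")
  assert_same_shape(source, target)
  if (!all(is.finite(source$pixels)) || !all(is.finite(target$pixels))) {
    stop("images must be finite", call. = FALSE)
  }
  similarity <- match.arg(similarity)

  theta <- 0
  coarse <- NULL; fine <- NULL; iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    coarse <- coarse_translation(source, target, grid = grid, theta = theta,
                                 k = k, threshold = threshold,
                                 max_corners = max_corners,
                                 match_gate = match_gate,
                                 response_form = response_form)
    fine <- fine_rotation(source, target, tau = coarse$tau, grid = grid,
                          similarity = similarity, hog_params = hog_params,
                          n_levels = n_levels)
    if (fine$theta == theta) break  # self-consistent fixed point
    theta <- fine$theta
  }
  best <- rigid_transform(fine$theta, coarse$tau[1L], coarse$tau[2L])
  registered <- resample(target, inverse_transform(best))

  src_corners <- detect_corners(source, k = k, threshold = threshold,
                                max_corners = max_corners,
                                response_form = response_form)
  reg_corners <- detect_corners(registered, k = k, threshold = threshold,
                                max_corners = max_corners,
                                response_form = response_form)
  tgt_corners <- detect_corners(target, k = k, threshold = threshold,
                                max_corners = max_corners,
                                response_form = response_form)
  fiducials <- match_corners(src_corners, reg_corners, max_pairs = omega,
                             gate_px = gate_px, warn_short = TRUE)
  if (nrow(fiducials) == 0L) {
    stop("no fiducial matches after registration; cannot assess accuracy",
         call. = FALSE)
  }
  fre <- compute_fre(fiducials, source$pixel_spacing)

  at_boundary <-
    fine$theta %in% range(grid$theta_values) ||
    any(coarse$tau %in% range(grid$tau_values))
  if (at_boundary) {
    warning("optimum on the search-grid boundary; the true transform may lie outside the grid",
            call. = FALSE)
  }
  structure(
    list(
      best_transform = best,
      mi_trace = fine$mi_trace,
      ed_surface = coarse$ed_surface,
      fre = fre,
      fiducials = fiducials,
      registered = registered,
      method = similarity,
      corner_counts = c(source = nrow(src_corners), target = nrow(tgt_corners),
                        registered = nrow(reg_corners)),
      at_boundary = at_boundary,
      iterations = iterations,
      config = list(grid = grid[c("tau_min", "tau_max", "tau_step",
                                  "theta_min", "theta_max", "theta_step")],
                    similarity = similarity, n_levels = n_levels,
                    hog_params = unclass(hog_params),
                    harris = list(k = k, threshold = threshold,
                                  max_corners = max_corners,
                                  match_gate = match_gate, gate_px = gate_px,
                                  response_form = response_form),
                    omega = omega, max_iter = max_iter)
    ),
    class = "hog_registration"
  )
}

#' @export
print.hog_registration <- function(x, ...) {
  cat(sprintf(
    "<hog_registration> method %s\n  theta = %g deg, tau = (%g, %g) px%s\n  FRE rms %.3g px, mean %.3g px (|Omega| = %d)\n",
    x$method, x$best_transform$theta, x$best_transform$tau_x,
    x$best_transform$tau_y, if (x$at_boundary) "  [at grid boundary]" else "",
    x$fre$rms, x$fre$mean, x$fre$omega
  ))
  invisible(x)
}

#' Write registration outputs to a directory
#'
#' Writes `result.json` (transform, FRE report, corner counts, config),
#' `mi_trace.csv`, `ed_surface.csv`, `fiducials.csv` and the resampled
#' moving image `registered.nii.gz`.
#'
#' @param result A `hog_registration`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_registration <- function(result, dir) {
  stopifnot(inherits(result, "hog_registration"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    transform = list(theta_deg = result$best_transform$theta,
                     tau_x_px = result$best_transform$tau_x,
                     tau_y_px = result$best_transform$tau_y),
    method = result$method,
    at_boundary = result$at_boundary,
    fre = result$fre[c("rms", "mean", "sd", "rms_mm", "mean_mm", "sd_mm",
                       "omega", "pixel_spacing")],
    corner_counts = as.list(result$corner_counts),
    mi_max = max(result$mi_trace$mi),
    config = result$config
  )
  jsonlite::write_json(payload, file.path(dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_mi_trace_csv(result$mi_trace, file.path(dir, "mi_trace.csv"))
  utils::write.csv(as.data.frame(result$ed_surface),
                   file.path(dir, "ed_surface.csv"), row.names = FALSE)
  write_corners_csv(result$fiducials, file.path(dir, "fiducials.csv"))
  save_image(result$registered, file.path(dir, "registered.nii.gz"))
  invisible(dir)
}
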