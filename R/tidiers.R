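#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a registration fit
#'
#' Returns the MI-vs-rotation trace as a tibble (one row per grid angle),
#' the curve whose argmax is the recovered rotation.
#'
#' @param x A `hog_registration` from [register()].
#' @param ... Unused.
#' @return Tibble with columns `theta` (degrees) and `mi` (bits).
#' @exportS3Method generics::tidy
tidy.hog_registration <- function(x, ...) {
  x$mi_trace
}

#' One-row summary of a registration fit
#'
#' @param x A `hog_registration` from [register()].
#' @param ... Unused.
#' @return One-row tibble: recovered `theta`, `tau_x`, `tau_y`, the MI at
#'   the optimum, the minimum corner distance of the coarse stage, FRE
#'   statistics, fiducial count, corner counts and flags.
#' @exportS3Method generics::glance
glance.hog_registration <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    theta = x$best_transform$theta,
    tau_x = x$best_transform$tau_x,
    tau_y = x$best_transform$tau_y,
    mi_max = max(x$mi_trace$mi),
    ed_min = min(x$ed_surface$ed),
    fre_rms = x$fre$rms,
    fre_mean = x$fre$mean,
    fre_sd = x$fre$sd,
    omega = x$fre$omega,
    n_corners_source = unname(x$corner_counts["source"]),
    n_corners_registered = unname(x$corner_counts["registered"]),
    at_boundary = x$at_boundary
  )
}

#' Tidy an FRE report
#'
#' @param x An `fre_report` from [compute_fre()].
#' @param ... Unused.
#' @return Tibble with one row per fiducial: `fiducial`, `error_px`,
#'   `error_mm`.
#' @exportS3Method generics::tidy
tidy.fre_report <- function(x, ...) {
  tibble::tibble(
    fiducial = seq_len(x$omega),
    error_px = x$per_fiducial_error,
    error_mm = x$per_fiducial_error * x$pixel_spacing
  )
}

#' One-row summary of an FRE report
#'
#' @param x An `fre_report` from [compute_fre()].
#' @param ... Unused.
#' @return One-row tibble with `rms`, `mean`, `sd` (px), their mm
#'   counterparts, and `omega`.
#' @exportS3Method generics::glance
glance.fre_report <- function(x, ...) {
  tibble::tibble(
    rms = x$rms, mean = x$mean, sd = x$sd,
    rms_mm = x$rms_mm, mean_mm = x$mean_mm, sd_mm = x$sd_mm,
    omega = x$omega
  )
}

#' Plot the MI-vs-rotation trace of a registration fit
#'
#' Line plot of mutual information against candidate rotation angle with
#' the recovered angle marked — the standard way to inspect whether the
#' similarity surface has a single, well-located peak.
#'
#' @param object A `hog_registration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hog_registration <- function(object, ...) {
  ggplot2::ggplot(object$mi_trace,
                  ggplot2::aes(x = .data$theta, y = .data$mi)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$best_transform$theta,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "rotation angle (degrees)",
      y = "mutual information (bits)",
      title = sprintf("MI trace (%s), recovered theta = %g deg",
                      object$method, object$best_transform$theta)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the coarse-stage corner-distance surface
#'
#' Heat map of the mean matched-corner distance over the translation grid;
#' the minimum marks the recovered shift.
#'
#' @param result A `hog_registration` or the list returned by
#'   [coarse_translation()].
#' @return A ggplot object.
#' @export
plot_ed_surface <- function(result) {
  surf <- result$ed_surface
  surf <- surf[is.finite(surf$ed), , drop = FALSE]
  ggplot2::ggplot(surf, ggplot2::aes(x = .data$tau_x, y = .data$tau_y,
                                     fill = .data$ed)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean ED (px)") +
    ggplot2::labs(x = "tau_x (px)", y = "tau_y (px)",
                  title = "Coarse-stage corner-distance surface") +
    ggplot2::theme_minimal()
}

#' Box plot of per-fiducial registration errors
#'
#' @param object An `fre_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fre_report <- function(object, ...) {
  df <- tidy.fre_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$error_px)) +
    ggplot2::geom_boxplot(width = 0.3, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "fiducial registration error (px)") +
    ggplot2::theme_minimal()
}
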