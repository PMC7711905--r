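#' Fiducial registration error
#'
#' Accuracy assessment over matched corner fiducials: for each pair the
#' per-fiducial error `e_k` is the Euclidean distance between the source
#' corner and its counterpart in the registered image. The report carries
#' the root mean square `sqrt(mean(e^2))` (the rooted sum-of-squared-
#' difference form, in distance units), the arithmetic mean, and the sample
#' (n - 1) standard deviation of the `e_k`, each in pixels and — scaled by
#' `pixel_spacing` — in millimetres.
#'
#' @param pairing A `fiducial_pairing` from [match_corners()] with at least
#'   one pair.
#' @param pixel_spacing Millimetres per pixel (> 0).
#' @return An `fre_report`: list with `per_fiducial_error` (px), `rms`,
#'   `mean`, `sd` (px), `rms_mm`, `mean_mm`, `sd_mm`, `omega`, and
#'   `pixel_spacing`. `sd` is `NA` for a single pair.
#' @examples
#' pr <- tibble::tibble(pair_id = 1:2, src_x = c(0, 0), src_y = c(0, 0),
#'                      tgt_x = c(3, 4), tgt_y = c(0, 0),
#'                      distance = c(3, 4))
#' class(pr) <- c("fiducial_pairing", class(pr))
#' compute_fre(pr)$rms  # sqrt(12.5)
#' @export
compute_fre <- function(pairing, pixel_spacing = 1.0) {
  if (!is.data.frame(pairing) || nrow(pairing) == 0L) {
    stop("`pairing` must contain at least one fiducial pair", call. = FALSE)
  }
  if (pixel_spacing <= 0) stop("`pixel_spacing` must be > 0", call. = FALSE)
  e <- sqrt((pairing$src_x - pairing$tgt_x)^2 +
              (pairing$src_y - pairing$tgt_y)^2)
  n <- length(e)
  rms <- sqrt(mean(e^2))
  m <- mean(e)
  s <- if (n >= 2L) stats::sd(e) else NA_real_
  structure(
    list(per_fiducial_error = e, rms = rms, mean = m, sd = s,
         rms_mm = rms * pixel_spacing, mean_mm = m * pixel_spacing,
         sd_mm = s * pixel_spacing, omega = n,
         pixel_spacing = pixel_spacing),
    class = "fre_report"
  )
}

#' @export
print.fre_report <- function(x, ...) {
  cat(sprintf(
    "<fre_report> |Omega| = %d\n  rms  %.4g px (%.4g mm)\n  mean %.4g +/- %.4g px (%.4g +/- %.4g mm)\n",
    x$omega, x$rms, x$rms_mm, x$mean, x$sd, x$mean_mm, x$sd_mm
  ))
  invisible(x)
}

#' Write per-fiducial errors in long (box-plot-ready) format
#'
#' One row per fiducial with its error in pixels and millimetres, plus a
#' `label` column so reports from several slice pairs can be concatenated
#' and box-plotted together.
#'
#' @param report An `fre_report`.
#' @param path Output CSV path.
#' @param label Grouping label written with every row.
#' @return `path`, invisibly.
#' @export
write_fre_csv <- function(report, path, label = "pair") {
  stopifnot(inherits(report, "fre_report"))
  df <- data.frame(
    label = label,
    fiducial = seq_len(report$omega),
    error_px = report$per_fiducial_error,
    error_mm = report$per_fiducial_error * report$pixel_spacing
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
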