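#' Plot a fitted midline
#'
#' Centers, the fitted polynomial midline, and its inflection points, drawn
#' in radiographic orientation (y increasing downward).
#'
#' @param object A `midline_fit`.
#' @param centers Optional tibble of the fitted centers (`x`, `y`) to
#'   overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot midline_fit
#' @export
autoplot.midline_fit <- function(object, centers = NULL, ...) {
  ys <- seq(object$domain[1], object$domain[2], length.out = 400)
  curve <- tibble(y = ys, x = predict(object, ys))
  infl <- find_inflections(object)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(color = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("Spinal midline (degree %d, RMS %.2f px)",
                                  object$degree, object$rms_residual))
  if (!is.null(centers))
    p <- p + ggplot2::geom_point(data = as_tibble(centers), shape = 1)
  if (length(infl) > 0L)
    p <- p + ggplot2::geom_hline(yintercept = infl, linetype = "dashed",
                                 color = "grey50")
  p
}

#' Plot a phantom with its ground truth
#'
#' Raster of the rendered image with the generating midline and box
#' outlines.
#'
#' @param object A `spine_phantom` from [generate_phantom()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spine_phantom
#' @export
autoplot.spine_phantom <- function(object, ...) {
  px <- object$image
  df <- tidyr::expand_grid(y = seq_len(nrow(px)) - 0.5,
                           x = seq_len(ncol(px)) - 0.5)
  df$value <- as.vector(t(px))
  ys <- seq(min(object$boxes$y_min), max(object$boxes$y_max), length.out = 300)
  mid <- tibble(y = ys, x = poly_eval(object$spec$curve_coefficients, ys))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_path(data = mid, color = "red") +
    ggplot2::geom_rect(data = as_tibble(object$boxes),
                       ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                                    ymin = .data$y_min, ymax = .data$y_max),
                       inherit.aes = FALSE, fill = NA, color = "green") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot a measurement comparison
#'
#' Per-case manual vs automated angles with the identity line — the
#' at-a-glance agreement view for a [difference_report()].
#'
#' @param report A list returned by [difference_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_agreement <- function(report, ...) {
  ggplot2::ggplot(report$per_case,
                  ggplot2::aes(x = .data$ref, y = .data$cmp)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "reference angle (deg)", y = "comparison angle (deg)",
                  title = sprintf("Mean |difference of averages| = %.2f deg",
                                  report$summary$delta_average))
}
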