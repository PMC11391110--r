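#' Build a run configuration
#'
#' Collects every tunable of the measurement pipeline into one list that is
#' embedded verbatim in each report, so a run is reproducible from its
#' report alone. Values can be loaded from a YAML file and overridden by
#' arguments (arguments win).
#'
#' @param file Optional YAML config file.
#' @param ... Named overrides of the defaults.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(file = NULL, ...) {
  defaults <- list(
    standard_size = c(900, 1900),
    enhance = "none",            # none | window | gamma | clahe
    window_lo = 2, window_hi = 98,
    gamma = 0.5, clahe_clip = 2,
    detector = "classical",      # classical | annotation
    threshold = NULL, min_area = NULL, max_area = NULL,
    outlier_dist = 60,
    refine_endplates = FALSE,
    degree = NULL,               # NULL = min(5, n - 1)
    tangent_at = "boundary",     # boundary | vertebra
    band_convention = "upper",
    clinical_convention = FALSE,
    diagnostic_threshold = 10,
    seed = 1L
  )
  cfg <- defaults
  if (!is.null(file)) {
    loaded <- yaml::read_yaml(file)
    cfg[names(loaded)] <- loaded
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Measure a radiograph end to end
#'
#' The full input-to-classification flow: read (or accept) the image,
#' standardize it to the working frame, optionally enhance contrast, obtain
#' vertebra boxes (classical detector or annotation file), fit the
#' polynomial midline to the box centers, measure the Cobb angle of every
#' inflection-bounded segment, classify the pattern and grade severity.
#'
#' @param image A file path, [spine_image()], or pixel matrix.
#' @param config A [run_config()].
#' @param boxes_path Optional annotation file; when given, detection is
#'   bypassed (`read_boxes()` is used). Coordinates are taken to be in the
#'   image's native frame and are mapped into the standardized frame.
#' @param boxes_format Annotation dialect for `boxes_path`.
#' @param report_path Optional path; when given the report is written as
#'   JSON.
#' @param overlay_path Optional path; when given the annotated overlay is
#'   rendered as PNG.
#' @return The report: a list with `measurements` (tibble),
#'   `classification` (one-row tibble), `model` (tidy summary), `settings`
#'   and `warnings`.
#' @export
run_measure <- function(image, config = run_config(),
                        boxes_path = NULL, boxes_format = NULL,
                        report_path = NULL, overlay_path = NULL) {
  warnings <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  img <- if (is.character(image)) read_image(image) else
    if (inherits(image, "spine_image")) image else spine_image(image)
  native_size <- c(ncol(img$pixels), nrow(img$pixels))
  img <- standardize(img, config$standard_size)
  if (config$enhance != "none") {
    img <- enhance_contrast(img, method = config$enhance,
                            window_lo = config$window_lo, window_hi = config$window_hi,
                            gamma = config$gamma, clahe_clip = config$clahe_clip)
  }
  boxes <- collect(
    if (!is.null(boxes_path)) {
      b <- read_boxes(boxes_path, format = boxes_format, image_size = native_size)
      std <- to_standard_coords(img, c(b$x_min, b$x_max, b$center_x),
                                c(b$y_min, b$y_max, b$center_y))
      nb <- nrow(b)
      b$x_min <- std$x[seq_len(nb)];            b$y_min <- std$y[seq_len(nb)]
      b$x_max <- std$x[nb + seq_len(nb)];       b$y_max <- std$y[nb + seq_len(nb)]
      b$center_x <- std$x[2 * nb + seq_len(nb)]; b$center_y <- std$y[2 * nb + seq_len(nb)]
      new_vertebra_boxes(b, image_size = config$standard_size, source = "annotation")
    } else {
      detect_classical(img, threshold = config$threshold,
                       min_area = config$min_area, max_area = config$max_area,
                       outlier_dist = config$outlier_dist)
    }
  )
  if (isTRUE(config$refine_endplates))
    boxes <- collect(refine_endplates_hough(img, boxes))
  model <- collect(fit_midline(box_centers(boxes), degree = config$degree))
  measurements <- measure_spine(model, boxes, tangent_at = config$tangent_at)
  classification <- classify_measurements(
    measurements,
    threshold = config$diagnostic_threshold,
    clinical_convention = config$clinical_convention,
    convention = config$band_convention
  )
  report <- list(
    image = if (is.character(image)) image else "<in-memory>",
    model = list(
      coefficients = pixel_coefficients(model),
      degree = model$degree,
      domain = model$domain,
      rms_residual = model$rms_residual,
      side_rule = "apex deviation from endpoint chord"
    ),
    measurements = dplyr::mutate(measurements, angle_deg = round(.data$angle_deg, 2)),
    classification = classification,
    severity = classification$severity,
    settings = unclass(config),
    warnings = warnings
  )
  if (!is.null(overlay_path))
    render_overlay(img, model, boxes, measurements, overlay_path)
  if (!is.null(report_path))
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "rows", force = TRUE)
  invisible(c(report, list(boxes = boxes, fit = model, image_std = img)))
}

#' Generate a phantom study triple on disk
#'
#' Writes the rendered phantom image (8-bit PNG), its box annotations
#' (JSON) and the analytic ground truth (JSON) into a directory, closing
#' the loop with [run_measure()].
#'
#' @param spec A [phantom_spec()], or NULL to construct one from
#'   `n_curves`/`angle_up`/`angle_low` via [phantom_from_angles()].
#' @param out_dir Output directory (created if needed).
#' @param n_curves,angle_up,angle_low,... Passed to [phantom_from_angles()]
#'   when `spec` is NULL.
#' @return Invisibly, a list with the phantom and the three file paths.
#' @export
run_phantom <- function(spec = NULL, out_dir, n_curves = 1,
                        angle_up = 20, angle_low = 0, ...) {
  if (is.null(spec))
    spec <- phantom_from_angles(n_curves = n_curves, angle_up = angle_up,
                                angle_low = angle_low, ...)
  ph <- generate_phantom(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    image = file.path(out_dir, "phantom.png"),
    boxes = file.path(out_dir, "boxes.json"),
    truth = file.path(out_dir, "truth.json")
  )
  write_image(ph$image, paths$image)
  write_annotations(ph$boxes, paths$boxes, format = "json")
  truth <- list(
    curve_coefficients = spec$curve_coefficients,
    inflection_ys = ph$truth$inflection_ys,
    segments = dplyr::mutate(ph$truth$segments,
                             angle_deg = round(.data$angle_deg, 2)),
    centers = ph$truth$centers
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(list(phantom = ph), paths))
}
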