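#' Tangent angle of the midline
#'
#' The deviation of the midline's tangent from the vertical image axis:
#' `atan(f'(y))` in degrees, in `(-90, 90)`.
#'
#' @param model A `midline_fit`.
#' @param y Vertical position(s) inside the fitted domain.
#' @return Angle(s) in degrees.
#' @export
tangent_angle <- function(model, y) {
  rad2deg(atan(predict(model, y, deriv = 1L)))
}

#' Cobb angle between two midline tangents
#'
#' The Cobb angle is classically the angle between the superior endplate of
#' the uppermost involved vertebra and the inferior endplate of the lowest;
#' since the angle between two lines equals the angle between their
#' perpendiculars, the tangent-line formulation
#' `|atan(f'(y_upper)) - atan(f'(y_lower))|` is equivalent.
#'
#' @param model A `midline_fit`.
#' @param y_upper,y_lower Boundary positions with `y_upper < y_lower`,
#'   both inside the domain.
#' @return The angle in degrees, in `[0, 180)`.
#' @export
cobb_angle <- function(model, y_upper, y_lower) {
  if (y_upper >= y_lower) abort("y_upper must be above (smaller than) y_lower")
  abs(tangent_angle(model, y_upper) - tangent_angle(model, y_lower))
}

#' Select the end vertebrae of a curve segment
#'
#' The upper (lower) end vertebra is the one whose center y is nearest the
#' segment's start (end) boundary; exact ties are broken toward the segment
#' interior.
#'
#' @param segment A one-row segment (list or tibble row) with `y_start`,
#'   `y_end`.
#' @param boxes A [new_vertebra_boxes()] tibble.
#' @return Named integer vector `c(upper = i, lower = j)` of 0-based
#'   vertebra indices.
#' @export
select_end_vertebrae <- function(segment, boxes) {
  cy <- boxes$center_y
  nearest <- function(target, toward_interior_up) {
    d <- abs(cy - target)
    cand <- which(d == min(d))
    # tie toward the interior: downward for an upper boundary, upward for lower
    i <- if (toward_interior_up) max(cand) else min(cand)
    boxes$index[i]
  }
  c(upper = nearest(segment$y_start, TRUE), lower = nearest(segment$y_end, FALSE))
}

#' Measure all Cobb angles of a spine
#'
#' Runs [segment_spine()] on the fitted midline and produces one Cobb
#' measurement per inflection-bounded segment. Regions are assigned from
#' the apex's vertebra-rank fraction (rank of the vertebra nearest the apex
#' over `n - 1`): with two or more segments the most superior apex is
#' thoracic and the most inferior lumbar (in-between segments labeled by
#' the 0.5 threshold); a lone segment is thoracic when its apex fraction is
#' below 0.5, lumbar otherwise.
#'
#' @param model A `midline_fit`.
#' @param boxes The [new_vertebra_boxes()] tibble the model was fitted to.
#' @param tangent_at `"boundary"` evaluates tangents exactly at the segment
#'   boundaries (domain ends and inflection points); `"vertebra"` evaluates
#'   them at the end vertebrae's center y.
#' @return A tibble sorted superior to inferior, one row per segment:
#'   `region`, `angle_deg`, `upper_vertebra`, `lower_vertebra`, `y_upper`,
#'   `y_lower`, `side`, `apex_y`, `method`.
#' @export
measure_spine <- function(model, boxes, tangent_at = c("boundary", "vertebra")) {
  tangent_at <- arg_match_one(tangent_at[1], c("boundary", "vertebra"), "tangent_at mode")
  segs <- segment_spine(model)
  n <- nrow(boxes)
  meas <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
    seg <- segs[i, ]
    ends <- select_end_vertebrae(seg, boxes)
    if (tangent_at == "boundary") {
      yu <- seg$y_start; yl <- seg$y_end
    } else {
      yu <- boxes$center_y[boxes$index == ends["upper"]]
      yl <- boxes$center_y[boxes$index == ends["lower"]]
    }
    ang <- if (yu < yl) cobb_angle(model, yu, yl) else 0
    apex_rank <- boxes$index[which.min(abs(boxes$center_y - seg$apex_y))]
    tibble(
      angle_deg = ang,
      upper_vertebra = unname(ends["upper"]), lower_vertebra = unname(ends["lower"]),
      y_upper = yu, y_lower = yl, side = seg$side, apex_y = seg$apex_y,
      apex_fraction = if (n > 1L) apex_rank / (n - 1L) else 0.5,
      method = "midline_tangent"
    )
  })
  meas$region <- label_regions(meas$apex_fraction)
  meas <- dplyr::arrange(meas, .data$y_upper)
  meas[, c("region", "angle_deg", "upper_vertebra", "lower_vertebra",
           "y_upper", "y_lower", "side", "apex_y", "method")]
}

#' Cobb angle from Hough endplate tilts
#'
#' The classical endplate construction, used as a cross-check of the
#' midline-tangent method: the absolute difference between the upper end
#' vertebra's upper-endplate tilt and the lower end vertebra's
#' lower-endplate tilt, as detected by [refine_endplates_hough()].
#'
#' @param boxes A box tibble carrying endplate tilts.
#' @param upper_index,lower_index 0-based indices of the end vertebrae.
#' @return The angle in degrees.
#' @export
cobb_from_endplates <- function(boxes, upper_index, lower_index) {
  up <- boxes$tilt_upper[boxes$index == upper_index]
  lo <- boxes$tilt_lower[boxes$index == lower_index]
  if (length(up) != 1L || length(lo) != 1L || is.na(up) || is.na(lo))
    abort("endplates unavailable for the requested vertebrae; run refine_endplates_hough() first")
  abs(up - lo)
}

#' Render the annotated overlay
#'
#' The reviewable output image: green vertebra boxes, the red midline
#' polyline (sampled every pixel of its domain), red tangent lines at each
#' measurement boundary extended 150 px either side, and the angle values
#' drawn beside their segments. Rendering is pure pixel arithmetic, so the
#' output bytes are identical across repeated calls with the same inputs.
#'
#' @param image A [spine_image()] or pixel matrix (grayscale background).
#' @param model A `midline_fit`.
#' @param boxes A [new_vertebra_boxes()] tibble.
#' @param measurements Tibble from [measure_spine()] (may have zero rows).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_overlay <- function(image, model, boxes, measurements, path) {
  px <- if (inherits(image, "spine_image")) image$pixels else image
  H <- nrow(px); W <- ncol(px)
  rgb <- array(px, dim = c(H, W, 3))
  green <- c(0, 0.9, 0); red <- c(1, 0.15, 0.15)

  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    rgb <- draw_rect(rgb, b$x_min, b$y_min, b$x_max, b$y_max, green)
  }
  ys <- seq(model$domain[1], model$domain[2], by = 1)
  xs <- predict(model, ys)
  rgb <- draw_points(rgb, xs, ys, red)
  for (i in seq_len(nrow(measurements))) {
    m <- measurements[i, ]
    for (y0 in c(m$y_upper, m$y_lower)) {
      x0 <- predict(model, y0)
      slope <- predict(model, y0, deriv = 1L)
      # unit vector along the tangent (dx, dy) ~ (slope, 1)
      nrm <- sqrt(1 + slope^2)
      rgb <- draw_segment(rgb, x0 - 150 * slope / nrm, y0 - 150 / nrm,
                          x0 + 150 * slope / nrm, y0 + 150 / nrm, red)
    }
    lab <- sprintf("%.1f", m$angle_deg)
    rgb <- draw_text(rgb, lab, x = min(W - 40, predict(model, m$apex_y) + 70),
                     y = m$apex_y, col = red)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("cannot write overlay: directory '%s' does not exist", dir))
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}

set_px <- function(rgb, rows, cols, col) {
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
  rows <- rows[ok]; cols <- cols[ok]
  if (length(rows) == 0L) return(rgb)
  for (ch in 1:3) rgb[cbind(rows, cols, ch)] <- col[ch]
  rgb
}

draw_points <- function(rgb, x, y, col) {
  set_px(rgb, round(y + 0.5), round(x + 0.5), col)
}

draw_segment <- function(rgb, x0, y0, x1, y1, col) {
  n <- max(2L, ceiling(max(abs(x1 - x0), abs(y1 - y0))) * 2L)
  t <- seq(0, 1, length.out = n)
  draw_points(rgb, x0 + t * (x1 - x0), y0 + t * (y1 - y0), col)
}

draw_rect <- function(rgb, x0, y0, x1, y1, col) {
  rgb <- draw_segment(rgb, x0, y0, x1, y0, col)
  rgb <- draw_segment(rgb, x0, y1, x1, y1, col)
  rgb <- draw_segment(rgb, x0, y0, x0, y1, col)
  draw_segment(rgb, x1, y0, x1, y1, col)
}

# 3x5 bitmap glyphs for angle labels (digits, dot, minus), doubled to 6x10.
glyph_rows <- list(
  "0" = c("111","101","101","101","111"), "1" = c("010","110","010","010","111"),
  "2" = c("111","001","111","100","111"), "3" = c("111","001","111","001","111"),
  "4" = c("101","101","111","001","001"), "5" = c("111","100","111","001","111"),
  "6" = c("111","100","111","101","111"), "7" = c("111","001","010","010","010"),
  "8" = c("111","101","111","101","111"), "9" = c("111","101","111","001","111"),
  "." = c("000","000","000","000","010"), "-" = c("000","000","111","000","000")
)

draw_text <- function(rgb, text, x, y, col, scale = 2L) {
  chars <- strsplit(text, "")[[1]]
  cx <- round(x)
  for (ch in chars) {
    g <- glyph_rows[[ch]]
    if (!is.null(g)) {
      for (r in 1:5) {
        bits <- strsplit(g[r], "")[[1]] == "1"
        for (cc in which(bits)) {
          rows <- round(y) + (r - 1L) * scale + seq_len(scale) - 3L * scale
          cols <- cx + (cc - 1L) * scale + seq_len(scale)
          rgb <- set_px(rgb, rep(rows, each = scale), rep(cols, times = scale), col)
        }
      }
    }
    cx <- cx + 4L * scale
  }
  rgb
}
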