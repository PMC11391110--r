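#' Construct / validate an ordered vertebra box table
#'
#' The canonical container for detected or annotated vertebral bodies: a
#' tibble with one row per vertebra, sorted superior to inferior (strictly
#' increasing `center_y`), with 0-based half-open pixel boxes. Columns:
#' `index` (0-based rank), `x_min`, `y_min`, `x_max`, `y_max`, `center_x`,
#' `center_y`, `tilt_upper`, `tilt_lower` (endplate tilts in degrees, NA
#' until [refine_endplates_hough()]), `confidence`.
#'
#' @param boxes A data frame with at least the corner columns.
#' @param image_size `c(W, H)` in px.
#' @param source Provenance tag (`"annotation"`, `"classical"`, ...).
#' @param min_boxes Minimum number of boxes required (3 for downstream
#'   midline fitting).
#' @return A `vertebra_boxes` tibble (attributes `image_size`, `source`).
#' @export
new_vertebra_boxes <- function(boxes, image_size, source = "annotation",
                               min_boxes = 3L) {
  b <- as_tibble(boxes)
  if (!all(c("x_min", "y_min", "x_max", "y_max") %in% names(b)))
    abort("boxes need columns x_min, y_min, x_max, y_max")
  if (any(b$x_min >= b$x_max) || any(b$y_min >= b$y_max))
    abort("degenerate box: require x_min < x_max and y_min < y_max")
  if (is.null(b[["center_x"]])) b$center_x <- (b$x_min + b$x_max) / 2
  if (is.null(b[["center_y"]])) b$center_y <- (b$y_min + b$y_max) / 2
  if (is.null(b[["tilt_upper"]])) b$tilt_upper <- NA_real_
  if (is.null(b[["tilt_lower"]])) b$tilt_lower <- NA_real_
  if (is.null(b[["confidence"]])) b$confidence <- 1
  b <- dplyr::arrange(b, .data$center_y)
  if (nrow(b) < min_boxes)
    abort(sprintf("insufficient vertebrae: %d box(es), need at least %d",
                  nrow(b), min_boxes))
  if (anyDuplicated(b$center_y))
    abort("two boxes share a center y; vertebra order is ambiguous")
  b$index <- seq_len(nrow(b)) - 1L
  b <- b[, c("index", "x_min", "y_min", "x_max", "y_max",
             "center_x", "center_y", "tilt_upper", "tilt_lower", "confidence")]
  structure(b, image_size = as.numeric(image_size), source = source,
            class = c("vertebra_boxes", class(b)))
}

#' Read vertebra box annotations
#'
#' Parses JSON, CSV, or YOLO-style normalized label files (see
#' [write_annotations()] for the dialects), denormalizes YOLO coordinates
#' with `image_size`, merges duplicate boxes (IoU > 0.8, keeping the higher
#' confidence, ties broken by larger area), and returns the boxes sorted by
#' center y.
#'
#' @param path Annotation file.
#' @param format `"json"`, `"csv"` or `"yolo"`; guessed from the extension
#'   when omitted.
#' @param image_size `c(W, H)`; required for YOLO, read from the file for
#'   JSON, and required for CSV.
#' @return A [new_vertebra_boxes()] tibble.
#' @export
read_boxes <- function(path, format = NULL, image_size = NULL) {
  if (!file.exists(path)) abort(sprintf("annotation file '%s' does not exist", path))
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               json = "json", csv = "csv", txt = "yolo", "json")
  format <- arg_match_one(format, c("json", "csv", "yolo"), "annotation format")
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    image_size <- image_size %||% as.numeric(obj$image_size)
    b <- as_tibble(obj$boxes)
  } else if (format == "csv") {
    if (is.null(image_size)) abort("image_size is required for CSV annotations")
    b <- readr::read_csv(path, show_col_types = FALSE)
  } else {
    if (is.null(image_size)) abort("image_size is required for YOLO labels")
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 5L)
    if (length(bad) > 0L)
      abort(sprintf("malformed YOLO label at line %d of '%s'", bad[1], path))
    num <- lapply(parts, function(p) suppressWarnings(as.numeric(p[2:5])))
    bad <- which(vapply(num, anyNA, logical(1)))
    if (length(bad) > 0L)
      abort(sprintf("malformed YOLO label at line %d of '%s'", bad[1], path))
    m <- do.call(rbind, num)
    W <- image_size[1]; H <- image_size[2]
    b <- tibble(
      x_min = (m[, 1] - m[, 3] / 2) * W, y_min = (m[, 2] - m[, 4] / 2) * H,
      x_max = (m[, 1] + m[, 3] / 2) * W, y_max = (m[, 2] + m[, 4] / 2) * H
    )
  }
  b <- merge_overlapping(b)
  new_vertebra_boxes(b, image_size = image_size, source = "annotation")
}

box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  iy <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (area_a + area_b - inter)
}

# Greedy duplicate merge: boxes with IoU > threshold collapse to the one
# with higher confidence (ties: larger area).
merge_overlapping <- function(b, iou_threshold = 0.8) {
  if (is.null(b[["confidence"]])) b$confidence <- 1
  area <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  ord <- order(-b$confidence, -area)
  keep <- logical(nrow(b))
  for (i in ord) {
    kept <- which(keep)
    if (length(kept) == 0L ||
        all(box_iou(b[rep(i, length(kept)), ], b[kept, ]) <= iou_threshold)) {
      keep[i] <- TRUE
    }
  }
  b[sort(which(keep)), ]
}

#' Detect vertebral bodies with a classical pipeline
#'
#' A learned detector is not required to exercise the measurement pipeline:
#' on reasonably clean radiograph-like images, vertebral bodies are the
#' dominant bright blobs along the spine. The pipeline is (1) global Otsu
#' threshold (or a user threshold), (2) 3x3 morphological opening, (3)
#' connected components, (4) gates on component area (defaults relative to
#' the area-weighted median component area, `[0.25, 4] x` it, so that many
#' small noise specks cannot shift the reference) and aspect ratio
#' (width/height in `[0.8, 4]`), (5) sort by centroid y, (6) rejection of
#' components whose centroid x deviates more than `outlier_dist` px from
#' the median of their neighbors, (7) axis-aligned bounding boxes with
#' centroid centers.
#'
#' @param image A [spine_image()] (standardized) or pixel matrix.
#' @param threshold Intensity threshold in `[0, 1]`; Otsu when NULL.
#' @param min_area,max_area Absolute component-area gates in px^2;
#'   median-relative defaults when NULL.
#' @param aspect_range Allowed width/height range.
#' @param outlier_dist Max centroid-x deviation from the neighbor median,
#'   px (default 60 at the 900 x 1900 standard size).
#' @return A [new_vertebra_boxes()] tibble with `source = "classical"`.
#' @export
detect_classical <- function(image, threshold = NULL,
                             min_area = NULL, max_area = NULL,
                             aspect_range = c(0.8, 4.0),
                             outlier_dist = 60) {
  px <- if (inherits(image, "spine_image")) image$pixels else image
  if (length(px) == 0L) abort("empty image")
  W <- ncol(px); H <- nrow(px)
  thr <- threshold %||% EBImage::otsu(EBImage::Image(t(px)), range = c(0, 1))
  mask <- EBImage::Image(t(px) > thr)
  mask <- EBImage::opening(mask, EBImage::makeBrush(3, shape = "box"))
  lab <- t(EBImage::imageData(EBImage::bwlabel(mask)))
  nlab <- max(lab)
  if (nlab == 0L) abort("insufficient vertebrae: no components above threshold")
  idx <- which(lab > 0)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  labs <- lab[idx]
  comp <- tibble(lab = labs, r = rows, c = cols) |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(
      area = dplyr::n(),
      x_min = min(.data$c) - 1, x_max = max(.data$c),
      y_min = min(.data$r) - 1, y_max = max(.data$r),
      center_x = mean(.data$c) - 0.5, center_y = mean(.data$r) - 0.5,
      .groups = "drop"
    )
  # reference area: area-weighted median of component areas, so that small
  # noise specks (many, but negligible total area) cannot drag the gates
  # away from the vertebra population
  ord <- order(comp$area)
  cum <- cumsum(comp$area[ord])
  med <- comp$area[ord][which(cum >= cum[length(cum)] / 2)[1]]
  min_area <- min_area %||% (0.25 * med)
  max_area <- max_area %||% (4 * med)
  asp <- (comp$x_max - comp$x_min) / (comp$y_max - comp$y_min)
  comp <- comp[comp$area >= min_area & comp$area <= max_area &
                 asp >= aspect_range[1] & asp <= aspect_range[2], ]
  comp <- dplyr::arrange(comp, .data$center_y)
  if (nrow(comp) >= 3L) {
    n <- nrow(comp)
    ok <- vapply(seq_len(n), function(i) {
      nb <- setdiff(max(1L, i - 2L):min(n, i + 2L), i)
      abs(comp$center_x[i] - median(comp$center_x[nb])) <= outlier_dist
    }, logical(1))
    comp <- comp[ok, ]
  }
  if (nrow(comp) < 3L)
    abort(sprintf("insufficient vertebrae: %d component(s) after filtering", nrow(comp)))
  comp$confidence <- pmin(1, comp$area / med)
  new_vertebra_boxes(comp[, c("x_min", "y_min", "x_max", "y_max",
                              "center_x", "center_y", "confidence")],
                     image_size = c(W, H), source = "classical")
}

#' Refine vertebral endplates with a line Hough transform
#'
#' For each box, an edge map (gradient-magnitude threshold) is computed in
#' a vertically padded window around the box, and a straight-line Hough
#' transform (rho resolution 1 px, theta resolution 1 degree, restricted to
#' within 30 degrees of horizontal) is accumulated separately over the
#' upper and lower halves of the window. The strongest accumulator peak in
#' each half gives the upper/lower endplate tilt in degrees (positive =
#' right side lower; sub-degree precision via parabolic interpolation
#' across the theta bins). When both endplates are found, the box center is
#' recomputed as the midpoint of the two detected line midpoints.
#'
#' @param image A [spine_image()] or pixel matrix.
#' @param boxes A [new_vertebra_boxes()] tibble.
#' @param pad_frac Vertical window padding as a fraction of box height.
#' @param gradient_quantile Edge threshold: quantile of the window's
#'   gradient magnitudes.
#' @param min_votes Minimum accumulator votes for a peak, as a fraction of
#'   the window width; below it the tilt is left unset (with a warning).
#' @param theta_window Max deviation from horizontal, degrees.
#' @return The box tibble with `tilt_upper`/`tilt_lower` filled in where
#'   endplates were found, and centers updated where both were.
#' @export
refine_endplates_hough <- function(image, boxes, pad_frac = 0.25,
                                   gradient_quantile = 0.9,
                                   min_votes = 0.3, theta_window = 30) {
  px <- if (inherits(image, "spine_image")) image$pixels else image
  H <- nrow(px); W <- ncol(px)
  out <- boxes
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    pad <- pad_frac * (b$y_max - b$y_min)
    r0 <- max(1L, floor(b$y_min - pad) + 1L); r1 <- min(H, ceiling(b$y_max + pad))
    c0 <- max(1L, floor(b$x_min) + 1L);       c1 <- min(W, ceiling(b$x_max))
    win <- px[r0:r1, c0:c1]
    if (nrow(win) < 5L || ncol(win) < 5L || diff(range(win)) < 1e-9) {
      warn(sprintf("vertebra %d: endplates not found (flat window)", b$index))
      next
    }
    gy <- win * 0; gx <- win * 0
    gy[2:(nrow(win) - 1L), ] <- (win[3:nrow(win), ] - win[1:(nrow(win) - 2L), ]) / 2
    gx[, 2:(ncol(win) - 1L)] <- (win[, 3:ncol(win)] - win[, 1:(ncol(win) - 2L)]) / 2
    gmag <- sqrt(gx^2 + gy^2)
    gthr <- quantile(gmag[gmag > 0], gradient_quantile, names = FALSE)
    cy_win <- b$center_y - (r0 - 1L)   # box center y inside the window
    vote_threshold <- min_votes * ncol(win)
    # one sub-pixel edge point per column and half: the gradient-magnitude
    # centroid around the strongest horizontal-ish edge response, so that a
    # slightly tilted endplate is not staircase-quantized to whole rows
    horiz <- abs(gy) > abs(gx) & gmag >= gthr
    edge_points <- function(rows) {
      pts_x <- numeric(0); pts_y <- numeric(0)
      for (cc in seq_len(ncol(win))) {
        cand <- rows[horiz[rows, cc]]
        if (length(cand) == 0L) next
        r_best <- cand[which.max(gmag[cand, cc])]
        nb <- intersect((r_best - 2L):(r_best + 2L), seq_len(nrow(win)))
        w <- gmag[nb, cc]
        pts_x <- c(pts_x, cc - 0.5)
        pts_y <- c(pts_y, sum((nb - 0.5) * w) / sum(w))
      }
      list(x = pts_x, y = pts_y)
    }
    fit_half <- function(rows) {
      pts <- edge_points(rows)
      if (length(pts$x) < 3L) return(NULL)
      hough_line_peak(pts$x, pts$y, theta_window = theta_window,
                      vote_threshold = vote_threshold)
    }
    all_rows <- seq_len(nrow(win))
    up <- fit_half(all_rows[all_rows - 0.5 < cy_win])
    lo <- fit_half(all_rows[all_rows - 0.5 >= cy_win])
    if (is.null(up) || is.null(lo))
      warn(sprintf("vertebra %d: endplate peak below threshold", b$index))
    if (!is.null(up)) out$tilt_upper[i] <- up$tilt
    if (!is.null(lo)) out$tilt_lower[i] <- lo$tilt
    if (!is.null(up) && !is.null(lo)) {
      # line midpoints at the window's central x, mapped back to image coords
      xc <- (ncol(win) / 2)
      y_up <- line_y_at(up, xc); y_lo <- line_y_at(lo, xc)
      out$center_x[i] <- xc + (c0 - 1L)
      out$center_y[i] <- (y_up + y_lo) / 2 + (r0 - 1L)
    }
  }
  out
}

# Accumulate a line Hough transform (rho = x cos phi + y sin phi) over the
# given points, phi within theta_window degrees of vertical-normal (i.e.
# near-horizontal lines), and return the strongest peak as tilt degrees
# (tilt = phi - 90, positive = right side lower) plus line parameters.
hough_line_peak <- function(x, y, theta_window = 30, vote_threshold = 0) {
  phis <- seq(90 - theta_window, 90 + theta_window, by = 1)
  phir <- deg2rad(phis)
  rho <- outer(x, cos(phir)) + outer(y, sin(phir))   # n_pts x n_phi
  rho_bin <- round(rho)
  counts <- matrix(0L, nrow = length(phis),
                   ncol = diff(range(rho_bin)) + 1L)
  rho0 <- min(rho_bin)
  for (j in seq_along(phis)) {
    tab <- tabulate(rho_bin[, j] - rho0 + 1L, nbins = ncol(counts))
    counts[j, ] <- tab
  }
  peak <- which(counts == max(counts), arr.ind = TRUE)[1, , drop = TRUE]
  if (counts[peak[1], peak[2]] < vote_threshold) return(NULL)
  j <- peak[1]
  # parabolic interpolation across theta at the peak's rho bin
  dphi <- 0
  if (j > 1L && j < length(phis)) {
    v <- counts[(j - 1L):(j + 1L), peak[2]]
    den <- v[1] - 2 * v[2] + v[3]
    if (den < 0) dphi <- 0.5 * (v[1] - v[3]) / den
  }
  phi <- phis[j] + dphi
  list(tilt = phi - 90, phi = phi, rho = peak[2] - 1L + rho0)
}

line_y_at <- function(peak, x) {
  phir <- deg2rad(peak$phi)
  (peak$rho - x * cos(phir)) / sin(phir)
}

#' Extract ordered box centers
#'
#' One `(x, y)` point per vertebra, superior to inferior. Centers refined
#' by [refine_endplates_hough()] are already stored in `center_x`/
#' `center_y`, so this is the single source of midline input points.
#'
#' @param boxes A [new_vertebra_boxes()] tibble.
#' @return A tibble with columns `x`, `y`.
#' @export
box_centers <- function(boxes) {
  tibble(x = boxes$center_x, y = boxes$center_y)
}
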