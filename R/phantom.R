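#' Specify a synthetic spine phantom
#'
#' A phantom is a radiograph-like grayscale image of an ordered
#' superior-to-inferior column of bright quasi-rectangular vertebral bodies
#' whose centers lie on a known parametric midline `x(y)` (a polynomial in
#' the vertical pixel coordinate `y`). Because the midline is known in
#' closed form, every Cobb angle of the phantom is available analytically
#' via [analytic_cobb()], which makes the phantom the ground-truth oracle
#' for the whole measurement pipeline.
#'
#' @param curve_coefficients Numeric vector `c0, c1, ..., cd` (ascending
#'   powers) of the generating midline `x(y) = sum(ck * y^k)`, in pixel
#'   coordinates. Degree at most 6.
#' @param n_vertebrae Integer number of vertebral bodies (>= 3; a typical
#'   thoracolumbar radiograph shows 12-17).
#' @param vertebra_size `c(width, height)` of each body in px.
#' @param spacing Vertical gap in px between consecutive bodies.
#' @param image_size `c(width, height)` of the rendered image in px;
#'   defaults to the 900 x 1900 standard working frame.
#' @param noise_sigma Std dev of additive Gaussian intensity noise (>= 0).
#' @param blur_sigma Std dev in px of the Gaussian blur applied to the
#'   noise-free rendering (>= 0).
#' @param foreground,background Intensity levels in `[0, 1]` of bone and
#'   soft-tissue background.
#' @param spacing_jitter Std dev in px of random perturbation of each
#'   body's vertical position (0 = perfectly uniform spacing).
#' @param center_jitter_sigma Std dev in px of random lateral displacement
#'   of each body's center about the midline, emulating annotation /
#'   placement noise. Ground-truth angles remain those of the midline.
#' @param tilt_deg Rotation in degrees of each rendered body about its
#'   center (scalar or length `n_vertebrae`; positive = right side lower).
#'   Box annotations stay axis-aligned.
#' @param seed Integer RNG seed governing noise and jitter.
#'
#' @return An object of class `phantom_spec` (a named list).
#' @seealso [generate_phantom()], [phantom_from_angles()]
#' @export
phantom_spec <- function(curve_coefficients = c(450),
                         n_vertebrae = 15L,
                         vertebra_size = c(110, 80),
                         spacing = 22,
                         image_size = c(900, 1900),
                         noise_sigma = 0,
                         blur_sigma = 1,
                         foreground = 0.85,
                         background = 0.25,
                         spacing_jitter = 0,
                         center_jitter_sigma = 0,
                         tilt_deg = 0,
                         seed = 1L) {
  spec <- structure(list(
    curve_coefficients = as.numeric(curve_coefficients),
    n_vertebrae = as.integer(n_vertebrae),
    vertebra_size = as.numeric(vertebra_size),
    spacing = as.numeric(spacing),
    image_size = as.integer(image_size),
    noise_sigma = as.numeric(noise_sigma),
    blur_sigma = as.numeric(blur_sigma),
    foreground = as.numeric(foreground),
    background = as.numeric(background),
    spacing_jitter = as.numeric(spacing_jitter),
    center_jitter_sigma = as.numeric(center_jitter_sigma),
    tilt_deg = as.numeric(tilt_deg),
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$n_vertebrae < 3L)
    abort("invalid phantom field 'n_vertebrae': must be >= 3")
  if (length(spec$curve_coefficients) < 1L || length(spec$curve_coefficients) > 7L)
    abort("invalid phantom field 'curve_coefficients': degree must be <= 6")
  if (spec$noise_sigma < 0)
    abort("invalid phantom field 'noise_sigma': must be >= 0")
  if (spec$blur_sigma < 0)
    abort("invalid phantom field 'blur_sigma': must be >= 0")
  if (any(spec$vertebra_size <= 0) || length(spec$vertebra_size) != 2L)
    abort("invalid phantom field 'vertebra_size': need positive (width, height)")
  if (any(spec$image_size <= 0) || length(spec$image_size) != 2L)
    abort("invalid phantom field 'image_size': need positive (width, height)")
  if (any(spec$foreground < 0 | spec$foreground > 1) ||
      any(spec$background < 0 | spec$background > 1))
    abort("invalid phantom field 'foreground'/'background': must lie in [0, 1]")
  layout <- phantom_layout(spec)
  half_w <- spec$vertebra_size[1] / 2
  if (any(layout$x - half_w < 0) || any(layout$x + half_w > spec$image_size[1]) ||
      layout$y_top_box < 0 || layout$y_bot_box > spec$image_size[2])
    abort("invalid phantom field 'curve_coefficients': vertebra boxes fall outside image bounds")
  invisible(spec)
}

# Deterministic (pre-jitter) layout: evenly spaced box-center y positions,
# vertically centered in the frame, with x on the generating midline.
phantom_layout <- function(spec) {
  n <- spec$n_vertebrae
  h <- spec$vertebra_size[2]
  span <- n * h + (n - 1L) * spec$spacing
  y_top_box <- (spec$image_size[2] - span) / 2
  y <- y_top_box + h / 2 + (seq_len(n) - 1L) * (h + spec$spacing)
  list(y = y, x = poly_eval(spec$curve_coefficients, y),
       y_top_box = y_top_box, y_bot_box = y_top_box + span)
}

#' Analytic Cobb angles of a polynomial midline
#'
#' Computes, in closed form, what the tangent-line Cobb construction yields
#' on a known polynomial midline `x(y)`: inflection points are the real
#' roots of `x''(y)` with a genuine sign change inside the vertical span
#' (found via the companion-matrix root solver), each inflection-bounded
#' segment gets the angle `|atan(x'(y_i)) - atan(x'(y_{i+1}))|` between the
#' tangents at its boundaries, and the lateral side of each segment's apex
#' is judged against the chord joining the midline's endpoints. Roots
#' within 0.5 px of a span endpoint are dropped as boundary-degenerate.
#'
#' @param curve_coefficients Ascending polynomial coefficients of `x(y)`.
#' @param y_span `c(y_top, y_bottom)` vertical span in px, `y_top < y_bottom`.
#' @return A list with `inflection_ys` (ordered numeric vector) and
#'   `segments`, a tibble with one row per segment: `region`, `angle_deg`,
#'   `side`, `y_start`, `y_end`, `apex_y`, `tangent_start`, `tangent_end`.
#' @export
analytic_cobb <- function(curve_coefficients, y_span) {
  coefs <- as.numeric(curve_coefficients)
  if (length(y_span) != 2L || y_span[2] <= y_span[1])
    abort("y_span must be (y_top, y_bottom) with y_top < y_bottom")
  y_top <- y_span[1]; y_bot <- y_span[2]
  d1 <- poly_deriv(coefs)
  d2 <- poly_deriv(d1)
  infl <- if (length(coefs) >= 3L)
    poly_real_roots(d2, y_top + 0.5, y_bot - 0.5) else numeric(0)
  bounds <- c(y_top, infl, y_bot)
  fx  <- function(y) poly_eval(coefs, y)
  fp  <- function(y) poly_eval(d1, y)
  chord <- function(y) fx(y_top) + (fx(y_bot) - fx(y_top)) * (y - y_top) / (y_bot - y_top)
  segs <- purrr::map_dfr(seq_len(length(bounds) - 1L), function(i) {
    a <- bounds[i]; b <- bounds[i + 1L]
    apex_candidates <- poly_real_roots(d1, a, b)
    apex <- if (length(apex_candidates) > 0L) {
      apex_candidates[which.max(abs(fx(apex_candidates) - chord(apex_candidates)))]
    } else if (abs(fp(a)) <= abs(fp(b))) a else b
    dev <- fx(apex) - chord(apex)
    tibble(
      y_start = a, y_end = b, apex_y = apex,
      side = if (dev > 0) 1L else if (dev < 0) -1L else 1L,
      tangent_start = rad2deg(atan(fp(a))),
      tangent_end   = rad2deg(atan(fp(b))),
      angle_deg = abs(rad2deg(atan(fp(a)) - atan(fp(b))))
    )
  })
  frac <- (segs$apex_y - y_top) / (y_bot - y_top)
  segs$region <- label_regions(frac)
  list(inflection_ys = infl,
       segments = segs[, c("region", "angle_deg", "side", "y_start", "y_end",
                           "apex_y", "tangent_start", "tangent_end")])
}

# Thoracic/lumbar labels from apex position fractions along the span.
# With >= 2 segments the most superior apex is thoracic and the most
# inferior lumbar; any in-between segment is labeled by the 0.5 threshold.
# A single segment is labeled by the threshold alone.
label_regions <- function(frac) {
  n <- length(frac)
  lab <- ifelse(frac < 0.5, "thoracic", "lumbar")
  if (n >= 2L) {
    lab[which.min(frac)] <- "thoracic"
    lab[which.max(frac)] <- "lumbar"
  }
  lab
}

#' Generate a synthetic spine phantom
#'
#' Renders the phantom described by a [phantom_spec()]: one bright blurred
#' quasi-rectangle per vertebral body on a darker background, plus additive
#' Gaussian noise, together with exact axis-aligned box annotations and the
#' analytic ground truth of the generating midline. Identical spec and seed
#' give bit-identical output; with jitter parameters at their defaults of
#' zero, boxes and ground truth do not depend on the seed at all.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `spine_phantom` with elements `image` (numeric
#'   `[y, x]` matrix in `[0, 1]`), `boxes` (a vertebra box tibble, see
#'   [read_boxes()] for the columns), `truth` (list with `inflection_ys`,
#'   `segments`, `centers`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  layout <- phantom_layout(spec)
  n <- spec$n_vertebrae
  w <- spec$vertebra_size[1]; h <- spec$vertebra_size[2]
  W <- spec$image_size[1]; H <- spec$image_size[2]

  jit <- with_seed(spec$seed, list(
    dy = if (spec$spacing_jitter > 0) rnorm(n, 0, spec$spacing_jitter) else numeric(n),
    dx = if (spec$center_jitter_sigma > 0) rnorm(n, 0, spec$center_jitter_sigma) else numeric(n),
    noise = if (spec$noise_sigma > 0) matrix(rnorm(W * H, 0, spec$noise_sigma), H, W) else NULL
  ))
  cy <- layout$y + jit$dy
  cx <- poly_eval(spec$curve_coefficients, cy) + jit$dx
  tilt <- rep_len(spec$tilt_deg, n)

  img <- matrix(spec$background, H, W)
  xs <- seq_len(W) - 0.5   # pixel-center coordinates
  ys <- seq_len(H) - 0.5
  for (i in seq_len(n)) {
    if (tilt[i] == 0) {
      rows <- which(ys >= cy[i] - h / 2 & ys < cy[i] + h / 2)
      cols <- which(xs >= cx[i] - w / 2 & xs < cx[i] + w / 2)
      img[rows, cols] <- spec$foreground
    } else {
      # rotate pixel centers into the body frame and test the rectangle
      th <- deg2rad(tilt[i])
      r0 <- max(1L, floor(cy[i] - h)); r1 <- min(H, ceiling(cy[i] + h))
      c0 <- max(1L, floor(cx[i] - w)); c1 <- min(W, ceiling(cx[i] + w))
      sub_x <- outer(rep(1, r1 - r0 + 1L), xs[c0:c1]) - cx[i]
      sub_y <- outer(ys[r0:r1], rep(1, c1 - c0 + 1L)) - cy[i]
      u <-  sub_x * cos(th) + sub_y * sin(th)
      v <- -sub_x * sin(th) + sub_y * cos(th)
      inside <- abs(u) < w / 2 & abs(v) < h / 2
      blk <- img[r0:r1, c0:c1]
      blk[inside] <- spec$foreground
      img[r0:r1, c0:c1] <- blk
    }
  }
  if (spec$blur_sigma > 0) {
    eb <- EBImage::gblur(EBImage::Image(t(img)), sigma = spec$blur_sigma)
    img <- t(EBImage::imageData(eb))
  }
  if (!is.null(jit$noise)) img <- img + jit$noise
  img <- pmin(pmax(img, 0), 1)

  boxes <- tibble(
    index = seq_len(n) - 1L,
    x_min = cx - w / 2, y_min = cy - h / 2,
    x_max = cx + w / 2, y_max = cy + h / 2,
    center_x = cx, center_y = cy,
    tilt_upper = NA_real_, tilt_lower = NA_real_,
    confidence = 1
  )
  boxes <- new_vertebra_boxes(boxes, image_size = spec$image_size, source = "phantom")

  truth <- analytic_cobb(spec$curve_coefficients, range(layout$y))
  truth$centers <- tibble(x = poly_eval(spec$curve_coefficients, layout$y), y = layout$y)

  structure(list(image = img, boxes = boxes, truth = truth, spec = spec),
            class = "spine_phantom")
}

#' Construct a phantom spec with requested Cobb angles
#'
#' Solves for generating-midline coefficients that realize a requested
#' curve pattern exactly: `n_curves = 0` gives a straight spine (all angles
#' zero); `n_curves = 1` a single quadratic arc whose tangent-line Cobb
#' angle equals `angle_up`; `n_curves = 2` an S-shaped cubic with one
#' interior inflection whose superior and inferior segment angles equal
#' `angle_up` and `angle_low`.
#'
#' @param n_curves 0, 1 or 2 curve segments.
#' @param angle_up,angle_low Requested Cobb angles in degrees.
#' @param apex_fraction For a single curve, the apex position as a fraction
#'   of the vertebral span (default 0.35: a thoracic apex; values above 0.5
#'   give a lumbar curve).
#' @param ... Further arguments passed to [phantom_spec()] (sizes, noise,
#'   seed, ...).
#' @return A [phantom_spec()] whose [analytic_cobb()] ground truth matches
#'   the requested angles to floating-point accuracy.
#' @export
phantom_from_angles <- function(n_curves = 1, angle_up = 20, angle_low = 0,
                                apex_fraction = 0.35, ...) {
  dots <- list(...)
  dots$curve_coefficients <- NULL
  # probe layout on a straight spine to learn the vertical span
  probe_args <- dots
  probe_args$curve_coefficients <- (dots$image_size %||% c(900, 1900))[1] / 2
  probe <- do.call(phantom_spec, probe_args)
  lay <- phantom_layout(probe)
  y1 <- lay$y[1]; y2 <- lay$y[length(lay$y)]; L <- y2 - y1
  W <- probe$image_size[1]

  coefs <- if (n_curves == 0) {
    c(0)
  } else if (n_curves == 1) {
    if (angle_up <= 0 || angle_up >= 180) abort("angle_up must lie in (0, 180)")
    if (apex_fraction <= 0 || apex_fraction >= 1) abort("apex_fraction must lie in (0, 1)")
    # quadratic arc f'(y) = m (y - y*), apex at the requested span fraction;
    # m solved so the end tangents subtend exactly the requested angle
    ystar <- y1 + apex_fraction * L
    gap <- function(m) atan(m * (y2 - ystar)) + atan(m * (ystar - y1)) -
      deg2rad(angle_up)
    m <- stats::uniroot(gap, c(0, 1e3), tol = 1e-14)$root
    c(m / 2 * ystar^2, -m * ystar, m / 2)     # expand m/2 (y - y*)^2
  } else if (n_curves == 2) {
    if (angle_up <= 0 || angle_low <= 0) abort("both angles must be > 0 for 2 curves")
    # tangent direction at the inflection chosen to balance end slopes
    t0 <- -deg2rad(max(angle_up, angle_low)) / 2
    s_star <- tan(t0)
    s_top <- tan(t0 + deg2rad(angle_up))
    s_bot <- tan(t0 + deg2rad(angle_low))
    # f'(y) = s* + k (y - y*)^2, vertex (= inflection) at y* = y1 + r L
    ratio <- (s_top - s_star) / (s_bot - s_star)   # = (r / (1 - r))^2
    r <- sqrt(ratio) / (1 + sqrt(ratio))
    ystar <- y1 + r * L
    k <- (s_top - s_star) / (y1 - ystar)^2
    # integrate: x(y) = s* y + k/3 (y - y*)^3 + C
    c(-k / 3 * ystar^3, s_star + k * ystar^2, -k * ystar, k / 3)
  } else {
    abort("n_curves must be 0, 1 or 2")
  }
  # center the midline horizontally inside the frame
  xr <- range(poly_eval(coefs, seq(y1, y2, length.out = 200)))
  coefs[1] <- coefs[1] + W / 2 - mean(xr)
  args <- dots
  args$curve_coefficients <- coefs
  do.call(phantom_spec, args)
}

#' Write vertebra box annotations
#'
#' Serializes an ordered vertebra box table to JSON, CSV, or YOLO-style
#' normalized label lines. JSON and CSV round-trip through [read_boxes()]
#' exactly (coordinates written at full double precision); YOLO labels
#' round-trip to the printed precision (6 decimals).
#'
#' @param boxes A vertebra box tibble (from a phantom, [read_boxes()], or
#'   [detect_classical()]).
#' @param path Output file path.
#' @param format One of `"json"`, `"csv"`, `"yolo"`.
#' @param image_size `c(W, H)` used to normalize YOLO coordinates and
#'   recorded in the JSON header; defaults to the table's own image size.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(boxes, path, format = c("json", "csv", "yolo"),
                              image_size = NULL) {
  format <- arg_match_one(format[1], c("json", "csv", "yolo"), "annotation format")
  if (nrow(boxes) == 0L) abort("cannot write an empty box list")
  image_size <- image_size %||% attr(boxes, "image_size") %||%
    abort("image_size required (not recorded on the box table)")
  if (format == "json") {
    payload <- list(
      image_size = as.integer(image_size),
      boxes = purrr::pmap(boxes[, c("index", "x_min", "y_min", "x_max", "y_max")], list)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else if (format == "csv") {
    readr::write_csv(boxes[, c("index", "x_min", "y_min", "x_max", "y_max")], path)
  } else {
    W <- image_size[1]; H <- image_size[2]
    lines <- sprintf("0 %.6f %.6f %.6f %.6f",
                     (boxes$x_min + boxes$x_max) / 2 / W,
                     (boxes$y_min + boxes$y_max) / 2 / H,
                     (boxes$x_max - boxes$x_min) / W,
                     (boxes$y_max - boxes$y_min) / H)
    writeLines(lines, path)
  }
  invisible(path)
}

#' @export
print.spine_phantom <- function(x, ...) {
  cat(sprintf("<spine_phantom> %d vertebrae, %dx%d px, degree-%d midline\n",
              x$spec$n_vertebrae, x$spec$image_size[1], x$spec$image_size[2],
              length(x$spec$curve_coefficients) - 1L))
  segs <- x$truth$segments
  for (i in seq_len(nrow(segs)))
    cat(sprintf("  %-9s %6.2f deg (side %+d)\n", segs$region[i],
                segs$angle_deg[i], segs$side[i]))
  invisible(x)
}
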