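#' Create a spine image record from a pixel matrix
#'
#' @param pixels Numeric `[y, x]` matrix with intensities in `[0, 1]`.
#' @param original_size `c(W, H)` the image had before any processing;
#'   defaults to the matrix dimensions.
#' @return An object of class `spine_image`: a list with `pixels`,
#'   `original_size`, `standard_size` (NULL until [standardize()]),
#'   `pad_offsets` `(left, top)` and `scale`.
#' @export
spine_image <- function(pixels, original_size = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort("pixels must be a numeric [y, x] matrix")
  if (length(pixels) == 0L) abort("zero-area image")
  structure(list(
    pixels = pixels,
    original_size = as.numeric(original_size %||% c(ncol(pixels), nrow(pixels))),
    standard_size = NULL,
    pad_offsets = c(0, 0),
    scale = 1
  ), class = "spine_image")
}

#' Read a grayscale radiograph
#'
#' Reads an 8- or 16-bit PNG or TIFF and rescales intensities to `[0, 1]`
#' by the container's bit depth. RGB inputs are converted to grayscale by
#' averaging the three channels.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A [spine_image()] (not yet standardized).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read image: '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      abort(sprintf("unsupported image format '.%s' (expected png/tif/tiff)", ext))
    ),
    error = function(e) abort(sprintf("failed to read '%s' as %s: %s", path, ext,
                                      conditionMessage(e)))
  )
  if (length(dim(arr)) == 3L) arr <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
  spine_image(arr)
}

#' Write a spine image to disk
#'
#' Intensities are held in `[0, 1]` internally and quantized only here:
#' 8-bit PNG by default, 16-bit TIFF on request.
#'
#' @param image A [spine_image()] or plain pixel matrix.
#' @param path Output path; `.png` or `.tif`/`.tiff` selects the container.
#' @param bits 8 (PNG) or 16 (TIFF).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 8L) {
  px <- if (inherits(image, "spine_image")) image$pixels else image
  px <- pmin(pmax(px, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = as.integer(bits))
  } else {
    abort(sprintf("unsupported output format '.%s' (expected png/tif/tiff)", ext))
  }
  invisible(path)
}

#' Standardize an image to the working frame
#'
#' Aspect-preserving bilinear rescale so the image fits inside the standard
#' frame (default 900 x 1900), followed by symmetric zero-padding
#' (letterboxing) to exactly that frame. Letterboxing rather than
#' anisotropic stretching is essential: stretching would distort every
#' downstream tangent and hence bias the Cobb angles. The scale factor and
#' pad offsets are recorded so detections can be mapped back to original
#' coordinates with [to_original_coords()].
#'
#' @param image A [spine_image()].
#' @param standard_size `c(W, H)` of the working frame.
#' @return The standardized [spine_image()]. Idempotent: standardizing an
#'   already-standard image is the identity.
#' @export
standardize <- function(image, standard_size = c(900, 1900)) {
  if (!inherits(image, "spine_image")) image <- spine_image(image)
  if (length(image$pixels) == 0L) abort("zero-area image")
  W <- ncol(image$pixels); H <- nrow(image$pixels)
  sw <- standard_size[1]; sh <- standard_size[2]
  s <- min(sw / W, sh / H)
  nw <- max(1L, round(W * s)); nh <- max(1L, round(H * s))
  px <- image$pixels
  if (nw != W || nh != H) {
    eb <- EBImage::resize(EBImage::Image(t(px)), w = nw, h = nh, antialias = TRUE)
    px <- t(EBImage::imageData(eb))
    px <- pmin(pmax(px, 0), 1)
  }
  left <- floor((sw - nw) / 2); top <- floor((sh - nh) / 2)
  out <- matrix(0, sh, sw)
  out[top + seq_len(nh), left + seq_len(nw)] <- px
  structure(list(
    pixels = out,
    original_size = image$original_size,
    standard_size = as.numeric(standard_size),
    pad_offsets = image$pad_offsets * s + c(left, top),  # compose affine maps
    scale = image$scale * s
  ), class = "spine_image")
}

#' Map points between original and standardized coordinates
#'
#' @param image A standardized [spine_image()].
#' @param x,y Coordinates (0-based px).
#' @return A tibble with columns `x`, `y` in the target frame.
#' @export
to_standard_coords <- function(image, x, y) {
  tibble(x = x * image$scale + image$pad_offsets[1],
         y = y * image$scale + image$pad_offsets[2])
}

#' @rdname to_standard_coords
#' @export
to_original_coords <- function(image, x, y) {
  tibble(x = (x - image$pad_offsets[1]) / image$scale,
         y = (y - image$pad_offsets[2]) / image$scale)
}

#' Enhance radiographic contrast
#'
#' The interactive contrast adjustment radiologists apply in a DICOM viewer
#' to bring out bony structure is reproduced here by three standard,
#' deterministic methods: percentile windowing (linear rescale of the
#' `[lo, hi]` intensity percentiles onto `[0, 1]` with clipping), gamma
#' correction (`pixel^gamma`), and CLAHE (tile-based adaptive histogram
#' equalization, 8 x 8 tiles). All methods are monotone nondecreasing in
#' intensity, so bone/background polarity is never inverted.
#'
#' @param image A [spine_image()] or pixel matrix.
#' @param method One of `"window"` (default), `"gamma"`, `"clahe"`.
#' @param window_lo,window_hi Percentiles (0-100) defining the window.
#' @param gamma Exponent for the gamma method (> 0).
#' @param clahe_clip CLAHE clip limit.
#' @return The enhanced [spine_image()], intensities in `[0, 1]`.
#' @export
enhance_contrast <- function(image, method = c("window", "gamma", "clahe"),
                             window_lo = 2, window_hi = 98,
                             gamma = 0.5, clahe_clip = 2) {
  method <- arg_match_one(method[1], c("window", "gamma", "clahe"), "enhancement method")
  if (!inherits(image, "spine_image")) image <- spine_image(image)
  px <- image$pixels
  if (method == "window") {
    if (window_lo >= window_hi) abort("window_lo must be < window_hi")
    q <- quantile(px, c(window_lo, window_hi) / 100, names = FALSE)
    px <- if (q[2] > q[1]) (px - q[1]) / (q[2] - q[1]) else px * 0
    px <- pmin(pmax(px, 0), 1)
  } else if (method == "gamma") {
    if (gamma <= 0) abort("gamma must be > 0")
    px <- px^gamma
  } else {
    # clahe needs dimensions divisible by the tile grid: pad by edge
    # replication, equalize, crop back
    H <- nrow(px); W <- ncol(px)
    Hp <- ceiling(H / 8) * 8; Wp <- ceiling(W / 8) * 8
    padded <- px[c(seq_len(H), rep(H, Hp - H)), c(seq_len(W), rep(W, Wp - W)),
                 drop = FALSE]
    eb <- EBImage::clahe(EBImage::Image(t(padded)), nx = 8, ny = 8,
                         limit = clahe_clip)
    px <- pmin(pmax(t(EBImage::imageData(eb))[seq_len(H), seq_len(W)], 0), 1)
  }
  image$pixels <- px
  image
}

#' @export
print.spine_image <- function(x, ...) {
  cat(sprintf("<spine_image> %dx%d px%s, range [%.3f, %.3f]\n",
              ncol(x$pixels), nrow(x$pixels),
              if (is.null(x$standard_size)) "" else
                sprintf(" (standardized, scale %.4f, pad %d,%d)",
                        x$scale, x$pad_offsets[1], x$pad_offsets[2]),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}
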