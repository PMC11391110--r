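#' Fit the polynomial spinal midline
#'
#' Ordinary least squares fit of lateral position `x` as a polynomial in
#' the vertical coordinate `y` through the vertebra centers. The spine is
#' quasi-vertical on an anteroposterior radiograph, so `x = f(y)` is the
#' single-valued orientation. For numerical conditioning the fit is
#' performed on `y` mapped affinely to `[-1, 1]`; all exposed quantities
#' (evaluations, derivatives, inflections) are in pixel units, with the
#' chain rule applied through the rescale.
#'
#' @param centers A data frame of center points: columns `x`, `y` (or
#'   `center_x`, `center_y`), e.g. from [box_centers()].
#' @param degree Polynomial degree, 1-6. Default `NULL` picks
#'   `min(5, n_points - 1)`: degree 5 supports up to 3 inflections
#'   (thoracic + lumbar + transitional curves). An explicitly requested
#'   degree exceeding `n_points - 1` is an error.
#' @return An object of class `midline_fit` with fields `coef_u`
#'   (coefficients on the `[-1, 1]` scale), `degree`, `domain`
#'   `(y_top, y_bottom)`, `rms_residual` (px), `n_points`.
#' @export
fit_midline <- function(centers, degree = NULL) {
  cs <- as_tibble(centers)
  if (!is.null(cs[["center_x"]]) && is.null(cs[["x"]]))
    cs <- dplyr::rename(cs, x = "center_x", y = "center_y")
  if (is.null(cs[["x"]]) || is.null(cs[["y"]])) abort("centers need columns x and y")
  n <- nrow(cs)
  if (is.unsorted(cs$y, strictly = TRUE)) {
    cs <- dplyr::arrange(cs, .data$y)
    if (anyDuplicated(cs$y)) abort("center y values must be strictly increasing")
  }
  requested <- !is.null(degree)
  degree <- degree %||% min(5L, n - 1L)
  if (degree < 1L || degree > 6L) abort("degree must be between 1 and 6")
  if (n < degree + 1L)
    abort(sprintf("insufficient vertebrae for degree %d: need %d centers, have %d",
                  degree, degree + 1L, n))
  y1 <- cs$y[1]; y2 <- cs$y[n]
  u <- 2 * (cs$y - y1) / (y2 - y1) - 1
  deg <- degree
  repeat {
    X <- outer(u, 0:deg, `^`)
    fit <- lm.fit(X, cs$x)
    if (!anyNA(fit$coefficients)) break
    if (deg == 1L) abort("degenerate centers: cannot fit even a line")
    warn(sprintf("rank-deficient fit at degree %d; lowering to %d", deg, deg - 1L))
    deg <- deg - 1L
  }
  structure(list(
    coef_u = unname(fit$coefficients),
    degree = deg,
    domain = c(y1, y2),
    rms_residual = sqrt(mean(fit$residuals^2)),
    n_points = n
  ), class = "midline_fit")
}

u_of_y <- function(model, y) {
  2 * (y - model$domain[1]) / diff(model$domain) - 1
}

#' Evaluate the midline or its derivatives
#'
#' Horner evaluation of `f`, `f' = dx/dy`, or `f'' = d2x/dy2` in pixel
#' units. Evaluation outside the fitted domain (extrapolation) is rejected.
#'
#' @param object A `midline_fit`.
#' @param y Vertical pixel positions inside the domain.
#' @param deriv 0, 1 or 2.
#' @param ... Unused.
#' @return Numeric vector of values (px, px/px, or px/px^2).
#' @export
predict.midline_fit <- function(object, y, deriv = 0L, ...) {
  if (!deriv %in% 0:2) abort("deriv must be 0, 1 or 2")
  eps <- 1e-9 * max(1, diff(object$domain))
  if (any(y < object$domain[1] - eps | y > object$domain[2] + eps))
    abort(sprintf("y outside the fitted domain [%.2f, %.2f]",
                  object$domain[1], object$domain[2]))
  co <- object$coef_u
  for (k in seq_len(deriv)) co <- poly_deriv(co)
  poly_eval(co, u_of_y(object, y)) * (2 / diff(object$domain))^deriv
}

#' Locate the midline's inflection points
#'
#' Real roots of `f''` strictly inside the fitted domain, located by a
#' sign-change scan at 1 px resolution refined by bisection to 1e-6 px.
#' Roots within 0.5 px of a domain endpoint are dropped as
#' boundary-degenerate. A degree <= 1 model has no inflections.
#'
#' @param model A `midline_fit`.
#' @return Ordered numeric vector of inflection y positions (possibly
#'   empty).
#' @export
find_inflections <- function(model) {
  if (model$degree <= 1L) return(numeric(0))
  # clamp curvature below numerical noise (px^-1) so an effectively straight
  # fit does not sprout sign changes from floating-point residue
  f2 <- function(y) {
    v <- predict(model, y, deriv = 2L)
    ifelse(abs(v) < 1e-12, 0, v)
  }
  roots <- scan_sign_changes(f2, model$domain[1], model$domain[2],
                             step = 1, tol = 1e-6)
  roots[roots > model$domain[1] + 0.5 & roots < model$domain[2] - 0.5]
}

#' Partition the midline into curve segments
#'
#' Segment boundaries are the domain endpoints plus the inflection points.
#' Within each segment the apex is the root of `f'` (the point of maximal
#' lateral excursion) when one exists, otherwise the boundary with the
#' smaller `|f'|`. The lateral `side` of a segment is the sign of the
#' apex's deviation from the chord joining the midline's values at the
#' full-domain endpoints (+1 by convention for zero deviation). The chord
#' rule is used rather than the sign of `f''` because consecutive
#' inflection-bounded segments alternate `f''` sign by construction, which
#' would make a "both curves toward the same side" pattern unrepresentable.
#'
#' @param model A `midline_fit`.
#' @return A tibble with one row per segment: `y_start`, `y_end`, `apex_y`,
#'   `side`, `tangent_start`, `tangent_end` (degrees).
#' @export
segment_spine <- function(model) {
  bounds <- c(model$domain[1], find_inflections(model), model$domain[2])
  fp <- function(y) {
    v <- predict(model, y, deriv = 1L)
    ifelse(abs(v) < 1e-12, 0, v)
  }
  fx <- function(y) predict(model, y)
  y_top <- model$domain[1]; y_bot <- model$domain[2]
  chord <- function(y) fx(y_top) + (fx(y_bot) - fx(y_top)) * (y - y_top) / (y_bot - y_top)
  purrr::map_dfr(seq_len(length(bounds) - 1L), function(i) {
    a <- bounds[i]; b <- bounds[i + 1L]
    apex_candidates <- scan_sign_changes(fp, a, b, step = 1, tol = 1e-6,
                                         include_touch = TRUE)
    apex_candidates <- apex_candidates[apex_candidates > a & apex_candidates < b]
    apex <- if (length(apex_candidates) > 0L) {
      apex_candidates[which.max(abs(fx(apex_candidates) - chord(apex_candidates)))]
    } else if (abs(fp(a)) <= abs(fp(b))) a else b
    dev <- fx(apex) - chord(apex)
    tibble(
      y_start = a, y_end = b, apex_y = apex,
      side = if (dev > 0) 1L else if (dev < 0) -1L else 1L,
      tangent_start = rad2deg(atan(fp(a))),
      tangent_end = rad2deg(atan(fp(b)))
    )
  })
}

#' @export
print.midline_fit <- function(x, ...) {
  cat(sprintf("<midline_fit> degree %d on %d centers, domain [%.1f, %.1f] px, RMS %.3g px\n",
              x$degree, x$n_points, x$domain[1], x$domain[2], x$rms_residual))
  invisible(x)
}

# Convert internal [-1,1]-scale coefficients to pixel-coordinate
# coefficients of x(y) by expanding (2(y - y1)/(y2 - y1) - 1)^k.
pixel_coefficients <- function(model) {
  a <- 2 / diff(model$domain)
  b <- -1 - 2 * model$domain[1] / diff(model$domain)   # u = a y + b
  out <- numeric(model$degree + 1L)
  for (k in 0:model$degree) {
    ck <- model$coef_u[k + 1L]
    if (ck == 0) next
    # (a y + b)^k expanded by the binomial theorem
    j <- 0:k
    out[j + 1L] <- out[j + 1L] + ck * choose(k, j) * a^j * b^(k - j)
  }
  out
}

#' Tidy a fitted midline
#'
#' @param x A `midline_fit`.
#' @param ... Unused.
#' @return One row per polynomial term of `x(y)` in pixel coordinates:
#'   `term`, `estimate`.
#' @method tidy midline_fit
#' @export
tidy.midline_fit <- function(x, ...) {
  co <- pixel_coefficients(x)
  tibble(term = paste0("y^", seq_along(co) - 1L), estimate = co)
}

#' @rdname tidy.midline_fit
#' @return For `glance`: a one-row tibble with `degree`, `n_points`,
#'   `rms_residual`, `y_top`, `y_bottom`, `n_inflections`.
#' @method glance midline_fit
#' @export
glance.midline_fit <- function(x, ...) {
  tibble(degree = x$degree, n_points = x$n_points,
         rms_residual = x$rms_residual,
         y_top = x$domain[1], y_bottom = x$domain[2],
         n_inflections = length(find_inflections(x)))
}
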