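#' Classify the scoliotic curve pattern
#'
#' Rule-based decision tree on the two reported Cobb angles (superior =
#' "upper", inferior = "lower"), with the diagnostic threshold strictly
#' above 10 degrees:
#' * no angle > 10: `no_scoliosis`;
#' * exactly one angle > 10: `thoracic` when the upper angle is the
#'   greater, `lumbar` otherwise;
#' * both angles > 10: `thoracolumbar` when the two curves deviate toward
#'   different sides, `combined` when toward the same side.
#'
#' `clinical_convention = TRUE` swaps the `thoracolumbar`/`combined` labels
#' of the two-curve branch, matching the more common clinical usage in
#' which a single same-direction double curve is called thoracolumbar.
#'
#' @param upper_angle,lower_angle Cobb angles in degrees (>= 0).
#' @param upper_side,lower_side Lateral sides (-1 or +1); required only
#'   when both angles exceed the threshold.
#' @param threshold Diagnostic threshold in degrees (strict inequality).
#' @param clinical_convention Swap the two-curve labels (default FALSE).
#' @return One of `"no_scoliosis"`, `"thoracic"`, `"lumbar"`,
#'   `"thoracolumbar"`, `"combined"`.
#' @export
classify_curves <- function(upper_angle, lower_angle,
                            upper_side = NA, lower_side = NA,
                            threshold = 10, clinical_convention = FALSE) {
  if (upper_angle < 0 || lower_angle < 0) abort("angles must be >= 0")
  up <- upper_angle > threshold
  lo <- lower_angle > threshold
  if (!up && !lo) return("no_scoliosis")
  if (xor(up, lo)) {
    return(if (upper_angle > lower_angle) "thoracic" else "lumbar")
  }
  if (is.na(upper_side) || is.na(lower_side))
    abort("side required: both angles exceed the threshold")
  same <- sign(upper_side) == sign(lower_side)
  if (clinical_convention) {
    if (same) "thoracolumbar" else "combined"
  } else {
    if (same) "combined" else "thoracolumbar"
  }
}

#' Grade scoliosis severity
#'
#' Standard severity bands on the Cobb angle: none up to 10 degrees, mild
#' above 10 up to 25, moderate above 25 up to 45, severe above 45. The
#' band edges at 25 and 45 are shared by adjacent bands in common usage;
#' the default `"upper"` convention makes each band upper-inclusive
#' (25 is mild, 45 is moderate), consistent with the strict ">10"
#' diagnosis rule; `"lower"` assigns shared edges to the higher band.
#'
#' @param angle Cobb angle in degrees (>= 0); when several measurements
#'   are reported, grade the maximum.
#' @param convention `"upper"` (default) or `"lower"`.
#' @return One of `"none"`, `"mild"`, `"moderate"`, `"severe"`.
#' @export
severity_grade <- function(angle, convention = c("upper", "lower")) {
  convention <- arg_match_one(convention[1], c("upper", "lower"), "band convention")
  if (any(angle < 0)) abort("angle must be >= 0")
  grade1 <- function(a) {
    if (convention == "upper") {
      if (a <= 10) "none" else if (a <= 25) "mild" else if (a <= 45) "moderate" else "severe"
    } else {
      if (a <= 10) "none" else if (a < 25) "mild" else if (a < 45) "moderate" else "severe"
    }
  }
  vapply(angle, grade1, character(1))
}

#' Classify a measurement table
#'
#' Applies [classify_curves()] and [severity_grade()] to the output of
#' [measure_spine()]: the two largest-angle measurements feed the
#' classifier (ordered superior/inferior; a lone measurement contributes
#' its angle on its own region's slot with 0 on the other), and severity is
#' graded on the maximum reported angle.
#'
#' @param measurements Tibble from [measure_spine()].
#' @param ... Passed to [classify_curves()] / [severity_grade()]
#'   (`threshold`, `clinical_convention`, `convention`).
#' @return A one-row tibble: `label`, `severity`, `upper_angle`,
#'   `lower_angle`, `upper_side`, `lower_side`.
#' @export
classify_measurements <- function(measurements, ...) {
  dots <- list(...)
  if (nrow(measurements) == 0L) abort("no measurements to classify")
  top <- measurements |>
    dplyr::slice_max(.data$angle_deg, n = 2L, with_ties = FALSE) |>
    dplyr::arrange(.data$y_upper)
  if (nrow(top) == 1L) {
    if (top$region[1] == "thoracic") {
      ua <- top$angle_deg[1]; la <- 0; us <- top$side[1]; ls <- NA
    } else {
      ua <- 0; la <- top$angle_deg[1]; us <- NA; ls <- top$side[1]
    }
  } else {
    ua <- top$angle_deg[1]; la <- top$angle_deg[2]
    us <- top$side[1]; ls <- top$side[2]
  }
  cls_args <- dots[names(dots) %in% c("threshold", "clinical_convention")]
  sev_args <- dots[names(dots) %in% c("convention")]
  label <- do.call(classify_curves,
                   c(list(upper_angle = ua, lower_angle = la,
                          upper_side = us, lower_side = ls), cls_args))
  severity <- do.call(severity_grade,
                      c(list(angle = max(measurements$angle_deg)), sev_args))
  tibble(label = label, severity = severity,
         upper_angle = ua, lower_angle = la,
         upper_side = if (is.na(us)) NA_integer_ else as.integer(us),
         lower_side = if (is.na(ls)) NA_integer_ else as.integer(ls))
}
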