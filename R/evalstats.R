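#' Summarize a column of angle measurements
#'
#' Average, minimum and maximum of the non-missing entries of one
#' measurement column — the per-set summary used when comparing manual and
#' automated measurement series.
#'
#' @param table A measurement data frame: columns `case`, `region`, and
#'   one or more angle columns (e.g. `manual`, `automated`,
#'   `automated_enhanced`), angles in degrees, cells optionally NA.
#' @param column Name of the angle column to summarize.
#' @return A one-row tibble: `average`, `minimum`, `maximum`, `n`.
#' @export
angle_summary <- function(table, column) {
  v <- table[[column]]
  if (is.null(v)) abort(sprintf("no column '%s' in the table", column))
  v <- v[!is.na(v)]
  if (length(v) == 0L) abort(sprintf("column '%s' has no non-missing values", column))
  if (any(v < 0)) abort("angles must be >= 0")
  tibble(average = mean(v), minimum = min(v), maximum = max(v), n = length(v))
}

#' Differences between two measurement columns
#'
#' Absolute differences of the per-set average/min/max summaries plus the
#' signed per-case differences (`cmp - ref`), matched on case id and
#' region.
#'
#' @param table A measurement data frame (see [angle_summary()]).
#' @param ref_column,cmp_column Names of the reference (e.g. manual) and
#'   comparison (e.g. automated) columns.
#' @return A list with `summary` (one-row tibble: `delta_average`,
#'   `delta_min`, `delta_max`, `n`) and `per_case` (tibble: `case`,
#'   `region`, `ref`, `cmp`, `difference`).
#' @export
difference_report <- function(table, ref_column, cmp_column) {
  t2 <- table[!is.na(table[[ref_column]]) | !is.na(table[[cmp_column]]), ]
  unmatched <- t2$case[is.na(t2[[ref_column]]) != is.na(t2[[cmp_column]])]
  if (length(unmatched) > 0L)
    abort(sprintf("case(s) present in one column only: %s",
                  paste(unique(unmatched), collapse = ", ")))
  pairs <- t2[!is.na(t2[[ref_column]]), ]
  if (nrow(pairs) == 0L) abort("no complete pairs")
  s_ref <- angle_summary(pairs, ref_column)
  s_cmp <- angle_summary(pairs, cmp_column)
  per_case <- tibble(
    case = pairs$case,
    region = pairs[["region"]] %||% NA_character_,
    ref = pairs[[ref_column]], cmp = pairs[[cmp_column]],
    difference = pairs[[cmp_column]] - pairs[[ref_column]]
  )
  list(
    summary = tibble(
      delta_average = abs(s_cmp$average - s_ref$average),
      delta_min = abs(s_cmp$minimum - s_ref$minimum),
      delta_max = abs(s_cmp$maximum - s_ref$maximum),
      n = nrow(pairs)
    ),
    per_case = per_case
  )
}

#' Paired significance test between two measurement columns
#'
#' Paired two-tailed t-test on the per-case differences (the measurements
#' are continuous and paired by radiograph), with a Wilcoxon signed-rank
#' alternative. When every difference is exactly zero the test cannot
#' reject and `t = 0, p = 1` is reported; a zero-variance nonzero shift
#' yields `p = 0` with an infinite statistic.
#'
#' @param table A measurement data frame (see [angle_summary()]).
#' @param col_a,col_b Names of the two columns to compare.
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @return A one-row tibble: `statistic`, `p_value`, `n`, `method`.
#' @export
paired_angle_test <- function(table, col_a, col_b, method = c("t", "wilcoxon")) {
  method <- arg_match_one(method[1], c("t", "wilcoxon"), "test")
  a <- table[[col_a]]; b <- table[[col_b]]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) abort(sprintf("need at least 3 complete pairs, have %d", n))
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble(statistic = 0, p_value = 1, n = n, method = method))
    }
    return(tibble(statistic = sign(mean(d)) * Inf, p_value = 0, n = n, method = method))
  }
  if (method == "t") {
    ht <- stats::t.test(a, b, paired = TRUE)
    tibble(statistic = unname(ht$statistic), p_value = ht$p.value, n = n, method = method)
  } else {
    ht <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
    tibble(statistic = unname(ht$statistic), p_value = ht$p.value, n = n, method = method)
  }
}

#' Read a measurement comparison table
#'
#' CSV with columns `case, region, manual, automated, automated_enhanced`
#' (angle columns optional/NA-able).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_measurement_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("case", "region") %in% names(tb)))
    abort("measurement table needs 'case' and 'region' columns")
  if (anyDuplicated(paste(tb$case, tb$region)))
    abort("case ids must be unique within each region")
  tb
}
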