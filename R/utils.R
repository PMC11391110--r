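# Internal helpers shared across modules.
#
# Coordinate conventions used throughout the package:
#   * image pixel arrays are numeric matrices indexed [row, col] = [y, x],
#     intensities in [0, 1], y increasing downward (radiographic convention);
#   * continuous pixel coordinates are 0-based: the pixel stored at
#     matrix position (r, c) covers [c-1, c) x [r-1, r) and has center
#     (c - 0.5, r - 0.5);
#   * boxes are half-open [x_min, x_max) x [y_min, y_max).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Polynomial coefficients are always stored ascending: c0, c1, ..., cd.
poly_eval <- function(coefs, x) {
  d <- length(coefs) - 1L
  out <- rep(coefs[d + 1L], length(x))
  if (d >= 1L) for (k in d:1) out <- out * x + coefs[k]
  out
}

poly_deriv <- function(coefs) {
  d <- length(coefs) - 1L
  if (d == 0L) return(0)
  coefs[-1L] * seq_len(d)
}

# Real roots of a polynomial strictly inside (lo, hi). Roots are taken from
# the companion-matrix solver (base polyroot) and screened for a genuine sign
# change, so even-multiplicity touch points are not reported.
poly_real_roots <- function(coefs, lo, hi, im_tol = 1e-7) {
  while (length(coefs) > 1L && abs(coefs[length(coefs)]) < 1e-300) {
    coefs <- coefs[-length(coefs)]
  }
  if (length(coefs) <= 1L) return(numeric(0))
  z <- polyroot(coefs)
  scale <- pmax(1, Mod(z))
  re <- Re(z)[abs(Im(z)) <= im_tol * scale]
  re <- sort(unique(round(re, 9)))
  re <- re[re > lo & re < hi]
  if (length(re) == 0L) return(re)
  probes <- c(lo, re, hi)
  mids <- (probes[-1] + probes[-length(probes)]) / 2
  signs <- sign(poly_eval(coefs, mids))
  re[signs[-length(signs)] * signs[-1] < 0]
}

# Bisection to locate a sign change of f in [a, b] to tolerance tol (px).
bisect_root <- function(f, a, b, tol = 1e-6) {
  fa <- f(a); fb <- f(b)
  if (fa == 0) return(a)
  if (fb == 0) return(b)
  stopifnot(fa * fb < 0)
  while (b - a > tol) {
    m <- (a + b) / 2
    fm <- f(m)
    if (fm == 0) return(m)
    if (fa * fm < 0) { b <- m; fb <- fm } else { a <- m; fa <- fm }
  }
  (a + b) / 2
}

# Scan f on a 1 px grid over [lo, hi] and refine every sign change by
# bisection; used for inflection and apex location on fitted midlines.
# Exact zeros at grid points count as roots only when the surrounding
# nonzero values change sign (or always, when include_touch = TRUE, as
# needed for apex location where a tangent zero is a root regardless).
scan_sign_changes <- function(f, lo, hi, step = 1, tol = 1e-6,
                              include_touch = FALSE) {
  if (hi <= lo) return(numeric(0))
  grid <- seq(lo, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  n <- length(grid)
  vals <- vapply(grid, f, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(n - 1L)) {
    v1 <- vals[i]; v2 <- vals[i + 1L]
    if (v1 == 0) {
      prev <- vals[seq_len(max(0L, i - 1L))]; prev <- prev[prev != 0]
      nxt <- vals[i:n]; nxt <- nxt[nxt != 0]
      change <- length(prev) > 0L && length(nxt) > 0L &&
        sign(prev[length(prev)]) != sign(nxt[1])
      if (include_touch || change) roots <- c(roots, grid[i])
    } else if (v2 != 0 && v1 * v2 < 0) {
      roots <- c(roots, bisect_root(f, grid[i], grid[i + 1L], tol))
    }
  }
  if (vals[n] == 0 && include_touch) roots <- c(roots, grid[n])
  sort(unique(roots))
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# match.arg with a friendlier error listing the supported values.
arg_match_one <- function(value, choices, what) {
  if (length(value) != 1L || !value %in% choices) {
    abort(sprintf("unknown %s '%s'; supported: %s", what,
                  paste(value, collapse = ","), paste(choices, collapse = ", ")))
  }
  value
}
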