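# Shared phantom fixtures, built in code at test time.

# Small, fast phantom frame used where full 900x1900 rendering is not the
# point: 12 vertebrae in a 300x640 frame.
small_spec <- function(curve_coefficients = c(150), ...) {
  args <- list(curve_coefficients = curve_coefficients, n_vertebrae = 12L,
               vertebra_size = c(40, 30), spacing = 12,
               image_size = c(300, 640), blur_sigma = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# A gentle cubic midline for the small frame: one interior inflection.
# x(y) = 150 + 3e-2 (y - 320) - 4e-7 (y - 320)^3, expanded to monomials.
small_cubic_coefs <- function(yc = 320, a1 = 3e-2, a3 = -4e-7, x0 = 150) {
  c(x0 - a1 * yc - a3 * yc^3,
    a1 + 3 * a3 * yc^2,
    -3 * a3 * yc,
    a3)
}

# Expand x(y) = x0 + sum b_k ((y - yc) / s)^k into ascending monomial
# coefficients of y; used to build random bounded test polynomials.
centered_poly_coefs <- function(b, yc, s, x0) {
  d <- length(b)
  out <- numeric(d + 1L)
  out[1] <- x0
  for (k in seq_len(d)) {
    ck <- b[k] / s^k
    j <- 0:k
    terms <- ck * choose(k, j) * (-yc)^(k - j)
    out[j + 1L] <- out[j + 1L] + terms
  }
  out
}

# Random in-bounds phantom spec for oracle-equivalence testing: a degree
# 1-5 midline with bounded lateral excursion around the frame center.
random_oracle_spec <- function(n_vertebrae = 15L, image_size = c(900, 1900),
                               max_degree = 5L) {
  n <- n_vertebrae
  h <- 80; sp <- 22
  span <- n * h + (n - 1L) * sp
  y1 <- (image_size[2] - span) / 2 + h / 2
  y2 <- y1 + (n - 1L) * (h + sp)
  yc <- (y1 + y2) / 2
  d <- sample.int(max_degree, 1)
  b <- runif(d, -1, 1) * 150 / seq_len(d)
  coefs <- centered_poly_coefs(b, yc, (y2 - y1) / 2, image_size[1] / 2)
  # recenter the lateral excursion and retry if it cannot fit
  xs <- poly_eval_test(coefs, seq(y1, y2, length.out = 200))
  coefs[1] <- coefs[1] + image_size[1] / 2 - mean(range(xs))
  spread <- diff(range(xs))
  if (spread > image_size[1] - 130) return(random_oracle_spec(n_vertebrae, image_size, max_degree))
  phantom_spec(curve_coefficients = coefs, n_vertebrae = n,
               vertebra_size = c(110, h), spacing = sp,
               image_size = image_size, blur_sigma = 0)
}

# Independent Horner evaluation for test-side arithmetic.
poly_eval_test <- function(coefs, x) {
  out <- rep(coefs[length(coefs)], length(x))
  if (length(coefs) > 1L) for (k in (length(coefs) - 1L):1) out <- out * x + coefs[k]
  out
}

poly_deriv_test <- function(coefs) {
  if (length(coefs) <= 1L) return(0)
  coefs[-1L] * seq_len(length(coefs) - 1L)
}

# Dense-grid brute-force oracle for the tangent-line Cobb construction on a
# known polynomial: boundaries located by sign change of f'' sampled every
# 0.01 px, angles from the tangents at the boundaries.
brute_force_cobb <- function(coefs, y_span, step = 0.01, edge_margin = 0.5) {
  d1 <- poly_deriv_test(coefs)
  d2 <- poly_deriv_test(d1)
  g <- seq(y_span[1], y_span[2], by = step)
  v <- poly_eval_test(d2, g)
  s <- sign(v)
  flip <- which(s[-1] * s[-length(s)] < 0)
  infl <- (g[flip] + g[flip + 1L]) / 2
  infl <- infl[infl > y_span[1] + edge_margin & infl < y_span[2] - edge_margin]
  bounds <- c(y_span[1], infl, y_span[2])
  th <- atan(poly_eval_test(d1, bounds)) * 180 / pi
  list(inflections = infl, angles = abs(diff(th)))
}

# In-bounds quartic midline for the 900x1900 frame with inflections at
# exactly y = 700 and y = 1200: f''(y) = k (y - 700)(y - 1200).
quartic_coefs <- function(k = 2e-9, a = 700, b = 1200, y_span = c(174, 1726)) {
  g <- function(y) y^3 / 3 - (a + b) * y^2 / 2 + a * b * y
  sl <- -k * (g(y_span[1]) + g(y_span[2])) / 2   # balance the end slopes
  coefs <- c(450, sl, k * a * b / 2, -k * (a + b) / 6, k / 12)
  xs <- poly_eval_test(coefs, seq(y_span[1], y_span[2], length.out = 200))
  coefs[1] <- coefs[1] + 450 - mean(range(xs))
  coefs
}
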