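test_that("an exact cubic is reproduced by a degree-5 fit", {
  coefs <- small_cubic_coefs()
  y <- seq(130, 510, length.out = 12)
  centers <- tibble::tibble(x = poly_eval_test(coefs, y), y = y)
  m <- fit_midline(centers, degree = 5)
  expect_lt(m$rms_residual, 1e-8)
  yy <- seq(130, 510, by = 0.5)
  expect_lt(max(abs(predict(m, yy) - poly_eval_test(coefs, yy))), 1e-8)
})

test_that("collinear centers give the two-point slope with zero residual", {
  centers <- tibble::tibble(x = c(10, 20, 30), y = c(0, 100, 200))
  m <- fit_midline(centers, degree = 1)
  expect_equal(m$rms_residual, 0, tolerance = 1e-12)
  expect_equal(predict(m, 150, deriv = 1L), 0.1, tolerance = 1e-12)
})

test_that("degree bounds and point counts are enforced", {
  centers <- tibble::tibble(x = rnorm(4), y = 1:4 * 10)
  expect_error(fit_midline(centers, degree = 6), "insufficient vertebrae")
  expect_error(fit_midline(centers, degree = 0), "degree")
  expect_error(fit_midline(centers, degree = 7), "degree")
  # default degree adapts to the point count
  expect_equal(fit_midline(centers)$degree, 3L)
  big <- tibble::tibble(x = rnorm(12), y = 1:12 * 10)
  expect_equal(fit_midline(big)$degree, 5L)
})

test_that("derivatives match central finite differences", {
  set.seed(9)
  y <- seq(100, 1700, length.out = 15)
  centers <- tibble::tibble(x = 450 + cumsum(rnorm(15, 0, 12)), y = y)
  m <- fit_midline(centers, degree = 5)
  h <- 1e-3
  for (y0 in c(300.5, 900.25, 1500.75)) {
    fd1 <- (predict(m, y0 + h) - predict(m, y0 - h)) / (2 * h)
    expect_equal(predict(m, y0, deriv = 1L), fd1, tolerance = 1e-5)
    fd2 <- (predict(m, y0 + h) - 2 * predict(m, y0) + predict(m, y0 - h)) / h^2
    expect_equal(predict(m, y0, deriv = 2L), fd2, tolerance = 1e-3)
  }
  expect_error(predict(m, 99), "domain")
  expect_error(predict(m, 1701), "domain")
})

test_that("inflections of known polynomials are located precisely", {
  # cubic: f'' linear with root exactly at the construction point
  coefs <- small_cubic_coefs(yc = 317.25)
  y <- seq(130, 510, length.out = 12)
  m <- fit_midline(tibble::tibble(x = poly_eval_test(coefs, y), y = y), degree = 3)
  expect_equal(find_inflections(m), 317.25, tolerance = 1e-5)
  # quadratic: constant nonzero f'', no inflections
  q <- fit_midline(tibble::tibble(x = 150 + 1e-4 * (y - 300)^2, y = y), degree = 2)
  expect_length(find_inflections(q), 0)
})

test_that("fitted inflections agree with a dense-grid scan for degree 5", {
  set.seed(31)
  for (rep in 1:10) {
    y <- seq(174, 1726, length.out = 15)
    b <- runif(5, -1, 1) * 150 / (1:5)
    coefs <- centered_poly_coefs(b, 950, 776, 450)
    m <- fit_midline(tibble::tibble(x = poly_eval_test(coefs, y), y = y), degree = 5)
    got <- find_inflections(m)
    bf <- brute_force_cobb(coefs, range(y))
    expect_equal(length(got), length(bf$inflections))
    if (length(got) == length(bf$inflections) && length(got) > 0)
      expect_equal(got, bf$inflections, tolerance = 0.01)
    expect_lte(length(got), m$degree - 2L)
  }
})

test_that("segmentation boundaries are endpoints plus inflections", {
  coefs <- small_cubic_coefs()
  y <- seq(130, 510, length.out = 12)
  m <- fit_midline(tibble::tibble(x = poly_eval_test(coefs, y), y = y), degree = 3)
  segs <- segment_spine(m)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$y_end[1], segs$y_start[2])
  expect_equal(segs$y_end[1], find_inflections(m))
  # straight model: one segment, equal tangents, side +1 by convention
  s <- fit_midline(tibble::tibble(x = rep(150, 5), y = seq(100, 500, 100)), degree = 1)
  seg1 <- segment_spine(s)
  expect_equal(nrow(seg1), 1L)
  expect_equal(seg1$tangent_start, seg1$tangent_end)
  expect_equal(seg1$side, 1L)
})

test_that("a quartic with two inflections yields three alternating segments", {
  # f''(y) = k (y - a)(y - b): inflections at 700 and 1200 by construction
  coefs <- quartic_coefs()
  y <- seq(174, 1726, length.out = 15)
  m <- fit_midline(tibble::tibble(x = poly_eval_test(coefs, y), y = y), degree = 5)
  segs <- segment_spine(m)
  expect_equal(nrow(segs), 3L)
  expect_equal(segs$y_start[2:3], c(700, 1200), tolerance = 1e-4)
  gt <- analytic_cobb(coefs, range(y))
  expect_equal(segs$side, gt$segments$side)
})

test_that("midline fitting is mirror- and shift-equivariant", {
  set.seed(12)
  y <- seq(174, 1726, length.out = 15)
  coefs <- centered_poly_coefs(runif(4, -1, 1) * 120 / (1:4), 950, 776, 450)
  centers <- tibble::tibble(x = poly_eval_test(coefs, y), y = y)
  m <- fit_midline(centers, degree = 5)
  # mirror: x -> W - x
  mm <- fit_midline(dplyr::mutate(centers, x = 900 - x), degree = 5)
  ys <- seq(200, 1700, by = 25)
  expect_equal(predict(mm, ys, deriv = 1L), -predict(m, ys, deriv = 1L),
               tolerance = 1e-6)
  expect_equal(find_inflections(mm), find_inflections(m), tolerance = 1e-6)
  s_m <- segment_spine(m); s_mm <- segment_spine(mm)
  # sides flip wherever the apex deviation is nonzero; a segment whose apex
  # sits on a domain endpoint has exactly zero chord deviation and carries
  # the +1 convention under both orientations
  dev <- abs(predict(m, s_m$apex_y) -
               (predict(m, 174) + (predict(m, 1726) - predict(m, 174)) *
                  (s_m$apex_y - 174) / (1726 - 174)))
  nondeg <- dev > 1e-9
  expect_equal(s_mm$side[nondeg], -s_m$side[nondeg])
  # vertical shift by delta moves everything by exactly delta, angles fixed
  delta <- 137.5
  ms <- fit_midline(dplyr::mutate(centers, y = y + delta), degree = 5)
  expect_equal(find_inflections(ms), find_inflections(m) + delta, tolerance = 1e-5)
  s1 <- segment_spine(m); s2 <- segment_spine(ms)
  expect_equal(s2$apex_y, s1$apex_y + delta, tolerance = 1e-5)
  expect_equal(s2$tangent_start, s1$tangent_start, tolerance = 1e-8)
  expect_equal(s2$tangent_end, s1$tangent_end, tolerance = 1e-8)
})

test_that("tidy and glance expose pixel-coordinate summaries", {
  coefs <- small_cubic_coefs()
  y <- seq(130, 510, length.out = 12)
  m <- fit_midline(tibble::tibble(x = poly_eval_test(coefs, y), y = y), degree = 3)
  td <- tidy(m)
  expect_equal(nrow(td), 4L)
  expect_equal(td$estimate, coefs, tolerance = 1e-6)
  gl <- glance(m)
  expect_equal(gl$degree, 3L)
  expect_equal(gl$n_inflections, 1L)
  expect_lt(gl$rms_residual, 1e-8)
})
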