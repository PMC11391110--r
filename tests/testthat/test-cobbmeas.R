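straight_fit <- function() {
  fit_midline(tibble::tibble(x = rep(450, 5), y = seq(200, 1000, 200)), degree = 1)
}

test_that("tangent angles follow atan of the slope", {
  s <- straight_fit()
  expect_equal(tangent_angle(s, 600), 0)
  m45 <- fit_midline(tibble::tibble(x = c(0, 100, 200), y = c(0, 100, 200)), degree = 1)
  expect_equal(tangent_angle(m45, 100), 45, tolerance = 1e-9)
  m33 <- fit_midline(tibble::tibble(x = tan(33 * pi / 180) * c(0, 100, 200),
                                    y = c(0, 100, 200)), degree = 1)
  expect_equal(tangent_angle(m33, 100), 33, tolerance = 1e-9)
})

test_that("a constructed quadratic yields the 33-degree worked case", {
  # boundary slopes -/+ tan(16.5 deg) across the span -> Cobb 33.0
  y1 <- 200; y2 <- 1600; yc <- (y1 + y2) / 2
  m <- 2 * tan(16.5 * pi / 180) / (y2 - y1)
  y <- seq(y1, y2, length.out = 15)
  centers <- tibble::tibble(x = 450 + m / 2 * (y - yc)^2, y = y)
  fit <- fit_midline(centers, degree = 2)
  expect_equal(cobb_angle(fit, y1, y2), 33, tolerance = 1e-9)
  expect_equal(cobb_angle(fit, y1, y2),
               abs(tangent_angle(fit, y1) - tangent_angle(fit, y2)))
  expect_error(cobb_angle(fit, y2, y1), "y_upper")
})

test_that("end vertebrae are the nearest centers with interior tie-break", {
  b <- new_vertebra_boxes(
    tibble::tibble(x_min = 0, y_min = seq(0, 900, 100),
                   x_max = 10, y_max = seq(40, 940, 100)),
    image_size = c(100, 1000))
  # centers at 20, 120, ..., 920
  expect_equal(select_end_vertebrae(list(y_start = 220, y_end = 720), b),
               c(upper = 2L, lower = 7L))
  # boundary midway between centers 3 (320) and 4 (420): interior tie-break
  expect_equal(unname(select_end_vertebrae(list(y_start = 370, y_end = 920), b)["upper"]), 4L)
  expect_equal(unname(select_end_vertebrae(list(y_start = 20, y_end = 470), b)["lower"]), 4L)
  expect_equal(select_end_vertebrae(list(y_start = 20, y_end = 920), b),
               c(upper = 0L, lower = 9L))
})

test_that("measure_spine matches analytic truth on noise-free phantoms", {
  # straight spine: one 0-degree measurement
  ph0 <- generate_phantom(phantom_spec(curve_coefficients = 450, n_vertebrae = 12L))
  m0 <- fit_midline(box_centers(ph0$boxes))
  meas0 <- measure_spine(m0, ph0$boxes)
  expect_equal(nrow(meas0), 1L)
  expect_lt(meas0$angle_deg, 1e-9)
  # S-curve: two measurements equal to the analytic segment angles
  spec <- phantom_from_angles(n_curves = 2, angle_up = 30, angle_low = 20)
  ph <- generate_phantom(spec)
  m <- fit_midline(box_centers(ph$boxes))
  meas <- measure_spine(m, ph$boxes)
  expect_equal(nrow(meas), 2L)
  expect_equal(meas$angle_deg, ph$truth$segments$angle_deg, tolerance = 1e-6)
  expect_equal(meas$region, c("thoracic", "lumbar"))
  expect_equal(meas$side, ph$truth$segments$side)
  # end vertebrae bracket the segments in order
  expect_true(all(meas$upper_vertebra < meas$lower_vertebra))
})

test_that("three-segment spines keep all measurements, sorted by level", {
  coefs <- quartic_coefs()
  spec <- phantom_spec(curve_coefficients = coefs, n_vertebrae = 15L, blur_sigma = 0)
  ph <- generate_phantom(spec)
  m <- fit_midline(box_centers(ph$boxes), degree = 5)
  meas <- measure_spine(m, ph$boxes)
  expect_equal(nrow(meas), 3L)
  expect_true(!is.unsorted(meas$y_upper))
  expect_equal(meas$angle_deg, ph$truth$segments$angle_deg, tolerance = 1e-6)
})

test_that("angles are invariant to uniform scaling and mirroring", {
  spec <- phantom_from_angles(n_curves = 2, angle_up = 24, angle_low = 14)
  ph <- generate_phantom(spec)
  centers <- box_centers(ph$boxes)
  m <- fit_midline(centers, degree = 5)
  meas <- measure_spine(m, ph$boxes)
  for (s in c(0.5, 2, 3.7)) {
    ms <- fit_midline(dplyr::mutate(centers, x = x * s, y = y * s), degree = 5)
    scaled <- dplyr::mutate(as.data.frame(ph$boxes) * s, index = ph$boxes$index,
                            confidence = 1)
    bs <- new_vertebra_boxes(scaled, image_size = c(900, 1900) * s)
    meas_s <- measure_spine(ms, bs)
    expect_equal(meas_s$angle_deg, meas$angle_deg, tolerance = 1e-9)
  }
  mirrored <- dplyr::mutate(centers, x = 900 - x)
  mb <- dplyr::mutate(as.data.frame(ph$boxes),
                      x_min = 900 - ph$boxes$x_max, x_max = 900 - ph$boxes$x_min,
                      center_x = 900 - ph$boxes$center_x)
  meas_m <- measure_spine(fit_midline(mirrored, degree = 5),
                          new_vertebra_boxes(mb, image_size = c(900, 1900)))
  expect_equal(meas_m$angle_deg, meas$angle_deg, tolerance = 1e-9)
  expect_equal(meas_m$side, -meas$side)
})

test_that("the Cobb angle obeys the triangle property across boundaries", {
  set.seed(8)
  y <- seq(174, 1726, length.out = 15)
  coefs <- centered_poly_coefs(runif(5, -1, 1) * 140 / (1:5), 950, 776, 450)
  m <- fit_midline(tibble::tibble(x = poly_eval_test(coefs, y), y = y), degree = 5)
  for (rep in 1:20) {
    abc <- sort(runif(3, 174, 1726))
    expect_lte(cobb_angle(m, abc[1], abc[3]),
               cobb_angle(m, abc[1], abc[2]) + cobb_angle(m, abc[2], abc[3]) + 1e-12)
  }
})

test_that("endplate-based Cobb angles cross-check the midline method", {
  expect_equal(abs(12 - (-21)), 33)  # the arithmetic the method encodes
  b <- new_vertebra_boxes(
    tibble::tibble(x_min = 0, y_min = c(0, 30, 60), x_max = 10, y_max = c(20, 50, 80),
                   tilt_upper = c(12, 0, NA), tilt_lower = c(0, 0, -21)),
    image_size = c(100, 100))
  expect_equal(cobb_from_endplates(b, 0L, 2L), 33)
  expect_equal(cobb_from_endplates(b, 1L, 1L), 0)
  expect_error(cobb_from_endplates(b, 2L, 0L), "endplates unavailable")

  # rendered tilted phantom whose body tilts equal the midline tangents:
  # the endplate route must then agree with the midline-tangent route
  coefs <- small_cubic_coefs(a1 = 6e-2, a3 = -8e-7)
  flat <- generate_phantom(small_spec(coefs))
  d1 <- poly_deriv_test(coefs)
  tilts <- atan(poly_eval_test(d1, flat$boxes$center_y)) * 180 / pi
  ph <- generate_phantom(small_spec(coefs, blur_sigma = 1, tilt_deg = tilts))
  ref <- refine_endplates_hough(ph$image, ph$boxes)
  m <- fit_midline(box_centers(ph$boxes), degree = 3)
  meas <- measure_spine(m, ph$boxes, tangent_at = "vertebra")
  seg <- meas[which.max(meas$angle_deg), ]
  ep <- cobb_from_endplates(ref, seg$upper_vertebra, seg$lower_vertebra)
  expect_lt(abs(ep - seg$angle_deg), 2.5)
})

test_that("overlay rendering is deterministic and complete", {
  spec <- phantom_from_angles(n_curves = 2, angle_up = 30, angle_low = 20,
                              blur_sigma = 0)
  ph <- generate_phantom(spec)
  m <- fit_midline(box_centers(ph$boxes))
  meas <- measure_spine(m, ph$boxes)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_overlay(ph$image, m, ph$boxes, meas, p1)
  render_overlay(ph$image, m, ph$boxes, meas, p2)
  expect_gt(file.size(p1), 0)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # golden check: the rendering of this fixed fixture is pinned by hash
  expect_equal(unname(tools::md5sum(p1)), "01b2daf69cd3ca7f409a9ecb1ba86257")
  # empty measurement list: boxes and midline only, still renders
  p3 <- withr::local_tempfile(fileext = ".png")
  render_overlay(ph$image, m, ph$boxes, meas[0, ], p3)
  expect_gt(file.size(p3), 0)
  expect_error(render_overlay(ph$image, m, ph$boxes, meas, "/nonexistent/dir/o.png"),
               "directory")
})
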