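test_that("a straight spine has constant centers and zero angles", {
  ph <- generate_phantom(phantom_spec(curve_coefficients = 450, n_vertebrae = 12L))
  expect_equal(nrow(ph$boxes), 12L)
  expect_true(all(ph$boxes$center_x == 450))
  expect_true(all(ph$truth$segments$angle_deg == 0))
  expect_length(ph$truth$inflection_ys, 0)
})

test_that("analytic angles of a cubic match hand-computed tangents", {
  # x(y) = 150 + a1 (y - yc) + a3 (y - yc)^3 with inflection exactly at yc
  yc <- 320; a1 <- 3e-2; a3 <- -4e-7
  coefs <- small_cubic_coefs(yc = yc, a1 = a1, a3 = a3)
  y1 <- 120; y2 <- 520
  gt <- analytic_cobb(coefs, c(y1, y2))
  expect_equal(gt$inflection_ys, yc, tolerance = 1e-9)
  fp <- function(y) a1 + 3 * a3 * (y - yc)^2
  exp_up <- abs(atan(fp(y1)) - atan(fp(yc))) * 180 / pi
  exp_lo <- abs(atan(fp(yc)) - atan(fp(y2))) * 180 / pi
  expect_equal(gt$segments$angle_deg, c(exp_up, exp_lo), tolerance = 1e-9)
  # additivity at the inflection: the two segments partition the span
  total <- abs(atan(fp(y1)) - atan(fp(yc))) + abs(atan(fp(yc)) - atan(fp(y2)))
  expect_equal(sum(gt$segments$angle_deg), total * 180 / pi, tolerance = 1e-9)
})

test_that("degenerate generating curves are handled", {
  flat <- analytic_cobb(c(450), c(100, 500))       # degree 0: one segment, 0 deg
  expect_equal(nrow(flat$segments), 1L)
  expect_equal(flat$segments$angle_deg, 0)
  lin <- analytic_cobb(c(100, 0.2), c(100, 500))   # linear: equal tangents
  expect_equal(lin$segments$angle_deg, 0, tolerance = 1e-12)
  expect_length(lin$inflection_ys, 0)
})

test_that("analytic segmentation agrees with a dense-grid brute force", {
  set.seed(20)
  y_span <- c(174, 1726)
  for (rep in 1:100) {
    d <- sample.int(6, 1)
    b <- runif(d, -1, 1) * 200 / seq_len(d)
    coefs <- centered_poly_coefs(b, mean(y_span), diff(y_span) / 2, 450)
    gt <- analytic_cobb(coefs, y_span)
    bf <- brute_force_cobb(coefs, y_span)
    expect_length(gt$inflection_ys, length(bf$inflections))
    if (length(gt$inflection_ys) == length(bf$inflections)) {
      expect_equal(gt$inflection_ys, bf$inflections, tolerance = 0.01)
      expect_equal(gt$segments$angle_deg, bf$angles, tolerance = 1e-6)
    }
  }
})

test_that("mirroring the curve preserves angles and flips sides", {
  coefs <- small_cubic_coefs()
  W <- 300
  mirrored <- -coefs
  mirrored[1] <- W + mirrored[1]   # x -> W - x
  a <- analytic_cobb(coefs, c(120, 520))
  b <- analytic_cobb(mirrored, c(120, 520))
  expect_equal(a$segments$angle_deg, b$segments$angle_deg, tolerance = 1e-9)
  expect_equal(a$segments$side, -b$segments$side)
  expect_equal(a$inflection_ys, b$inflection_ys, tolerance = 1e-9)
})

test_that("phantom generation is deterministic and noise is seed-only", {
  spec <- small_spec(noise_sigma = 0.05, seed = 11L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image, b$image)
  expect_identical(as.data.frame(a$boxes), as.data.frame(b$boxes))
  spec2 <- spec; spec2$seed <- 12L
  c2 <- generate_phantom(spec2)
  expect_identical(as.data.frame(a$boxes), as.data.frame(c2$boxes))
  expect_identical(a$truth$segments, c2$truth$segments)
  expect_false(identical(a$image, c2$image))
})

test_that("invalid phantom specs fail naming the offending field", {
  expect_error(phantom_spec(n_vertebrae = 2), "n_vertebrae")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(curve_coefficients = rep(1, 8)), "curve_coefficients")
  # a curve running off the frame edge is rejected as out of bounds
  expect_error(phantom_spec(curve_coefficients = c(100, 0.5)), "bounds")
})

test_that("annotations round-trip through JSON, CSV and YOLO", {
  ph <- generate_phantom(small_spec(small_cubic_coefs()))
  for (fmt in c("json", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_annotations(ph$boxes, path, format = fmt)
    back <- read_boxes(path, format = fmt, image_size = c(300, 640))
    for (col in c("x_min", "y_min", "x_max", "y_max"))
      expect_equal(back[[col]], ph$boxes[[col]], tolerance = 1e-9)
  }
  path <- withr::local_tempfile(fileext = ".txt")
  write_annotations(ph$boxes, path, format = "yolo")
  back <- read_boxes(path, format = "yolo", image_size = c(300, 640))
  for (col in c("x_min", "y_min", "x_max", "y_max"))
    expect_equal(back[[col]], ph$boxes[[col]], tolerance = 1e-5 * 640)
})

test_that("YOLO normalization follows the label arithmetic", {
  b <- new_vertebra_boxes(
    tibble::tibble(x_min = c(440, 440, 440), y_min = c(100, 200, 300),
                   x_max = c(460, 460, 460), y_max = c(130, 230, 330)),
    image_size = c(900, 1900), min_boxes = 3L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_annotations(b, path, format = "yolo")
  first <- as.numeric(strsplit(readLines(path)[1], " ")[[1]])
  expect_equal(first[2], 450 / 900)           # exact at 6 decimals
  expect_lt(abs(first[3] - 115 / 1900), 1e-6)  # printed precision
  expect_lt(abs(first[4] - 20 / 900), 1e-6)
  expect_lt(abs(first[5] - 30 / 1900), 1e-6)
})

test_that("empty box lists and unknown formats are rejected", {
  ph <- generate_phantom(small_spec())
  expect_error(write_annotations(ph$boxes[0, ], tempfile(), format = "json"), "empty")
  expect_error(write_annotations(ph$boxes, tempfile(), format = "voc"), "supported")
})

test_that("phantom_from_angles realizes requested angles exactly", {
  spec1 <- phantom_from_angles(n_curves = 1, angle_up = 33)
  gt1 <- generate_phantom(spec1)$truth
  expect_equal(nrow(gt1$segments), 1L)
  expect_equal(gt1$segments$angle_deg, 33, tolerance = 1e-9)
  spec2 <- phantom_from_angles(n_curves = 2, angle_up = 30, angle_low = 20)
  gt2 <- generate_phantom(spec2)$truth
  expect_equal(gt2$segments$angle_deg, c(30, 20), tolerance = 1e-9)
  expect_equal(gt2$segments$region, c("thoracic", "lumbar"))
  spec0 <- phantom_from_angles(n_curves = 0)
  expect_true(all(generate_phantom(spec0)$truth$segments$angle_deg == 0))
})
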