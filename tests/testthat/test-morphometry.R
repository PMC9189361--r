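test_that("F-value analytics: circle, ellipse, square", {
  circ <- shape_metrics(generate_tumor_mask("circle", size_px = 128, r = 50))
  expect_lte(circ$f_value, 0.03)
  expect_gte(circ$f_value, 0)
  expect_equal(circ$area_tumor, pi * 50^2, tolerance = 0.01)

  ell <- shape_metrics(generate_tumor_mask("ellipse", size_px = 128,
                                           a = 40, b = 20))
  expect_equal(ell$f_value, 0.50, tolerance = 0.03 / 0.50)
  expect_equal(ell$area_tumor, pi * 40 * 20, tolerance = 0.01)

  sq <- shape_metrics(generate_tumor_mask("square", size_px = 128, side = 60))
  expect_equal(sq$f_value, 1 - 2 / pi, tolerance = 0.03 / (1 - 2 / pi))
  expect_equal(sq$area_tumor, 3600)
  # square perimeter: 4 sides of 59 px steps along the contour
  expect_equal(sq$perimeter, 4 * 59, tolerance = 0.01)
})

test_that("long axis matches the all-pairs Feret oracle", {
  expect_equal(long_axis(tumor_mask(matrix(c(FALSE, TRUE, FALSE, FALSE), 2))), 0)

  circ <- generate_tumor_mask("circle", size_px = 128, r = 50)
  expect_equal(long_axis(circ), 100, tolerance = 2 / 100)
  expect_equal(long_axis(circ), feret_oracle(circ))

  ell <- generate_tumor_mask("ellipse", size_px = 128, a = 40, b = 20)
  expect_equal(long_axis(ell), 80, tolerance = 2 / 80)
  expect_equal(long_axis(ell), feret_oracle(ell))

  for (seed in 1:8) {
    m <- random_small_mask(seed)
    expect_equal(long_axis(m), feret_oracle(m))
  }
})

test_that("minimum enclosing circle agrees with the brute-force oracle", {
  for (seed in 1:12) {
    m <- random_small_mask(seed)
    pts <- methylmorph:::boundary_points(m)
    got <- min_enclosing_circle(pts)
    ref <- mec_oracle(pts)
    expect_equal(got$radius, ref$radius, tolerance = 1e-6)
    d <- sqrt(sum((got$center - ref$center)^2))
    expect_lt(d, 1e-4 * (1 + ref$radius))
    # every boundary point really is enclosed
    dists <- sqrt((pts[, 1] - got$center[1])^2 + (pts[, 2] - got$center[2])^2)
    expect_lte(max(dists), got$radius * (1 + 1e-9) + 1e-7)
  }
})

test_that("F is invariant under translation, 90-degree rotation, and scaling", {
  base <- generate_tumor_mask("ellipse", size_px = 128, a = 40, b = 20)
  f0 <- shape_metrics(base)$f_value

  shifted <- matrix(FALSE, 160, 160)
  shifted[11:138, 21:148] <- as.logical(base)
  expect_equal(shape_metrics(tumor_mask(shifted))$f_value, f0)

  rotated <- t(as.matrix(base))[ncol(base):1, ]
  expect_equal(shape_metrics(tumor_mask(rotated))$f_value, f0)

  # uniform scaling: same axis ratio at growing size
  for (a in c(30, 45, 60)) {
    m <- generate_tumor_mask("ellipse", size_px = 2 * (a + 4), a = a, b = a / 2)
    expect_equal(shape_metrics(m)$f_value, f0, tolerance = 0.02 / f0)
  }
})

test_that("F decreases towards 0 as an ellipse approaches a circle", {
  fs <- vapply(c(0.25, 0.5, 0.75, 1), function(ratio) {
    m <- generate_tumor_mask("ellipse", size_px = 96, a = 40, b = 40 * ratio)
    shape_metrics(m)$f_value
  }, numeric(1))
  expect_true(all(diff(fs) < 0))
  expect_lt(fs[4], 0.04)
})

test_that("selected area always dominates tumor area", {
  for (seed in 1:10) {
    m <- generate_tumor_mask("perturbed_blob", size_px = 96, r = 25,
                             perturbation = runif(1, 0, 0.4), seed = seed)
    sm <- shape_metrics(m)
    expect_gte(sm$area_selected, sm$area_tumor)
    expect_gte(sm$f_value, 0)
    expect_lt(sm$f_value, 1)
  }
})

test_that("a blob with zero perturbation reproduces its base circle", {
  blob <- generate_tumor_mask("perturbed_blob", size_px = 96, r = 30,
                              perturbation = 0, seed = 5)
  circ <- generate_tumor_mask("circle", size_px = 96, r = 30)
  expect_identical(as.matrix(blob), as.matrix(circ))
})

test_that("masks reject shapes off canvas and disconnected foregrounds", {
  expect_error(generate_tumor_mask("circle", size_px = 64, r = 32), "margin")
  two <- matrix(FALSE, 8, 8); two[2, 2] <- TRUE; two[6, 6] <- TRUE
  expect_error(tumor_mask(two), "exactly one")
  expect_error(tumor_mask(matrix(FALSE, 4, 4)), "no foreground")
})

test_that("holes are filled before measurement", {
  solid <- generate_tumor_mask("circle", size_px = 64, r = 20)
  holed <- as.matrix(solid)
  holed[31:34, 31:34] <- FALSE
  expect_equal(shape_metrics(tumor_mask(holed))$area_tumor,
               shape_metrics(solid)$area_tumor)
})

test_that("caliper volume formula and its guards", {
  expect_equal(tumor_volume(10, 20), 1000)
  expect_equal(tumor_volume(1, 1), 0.5)
  expect_equal(tumor_volume(7.3, 11.1), 7.3^2 * 11.1 / 2)
  expect_error(tumor_volume(0, 5), "positive")
  expect_error(tumor_volume(12, 5), "exceed")
})

test_that("mask images round-trip through PNG and TIFF", {
  m <- generate_tumor_mask("ellipse", size_px = 48, a = 15, b = 8)
  for (ext in c(".png", ".tif")) {
    path <- withr::local_tempfile(fileext = ext)
    write_mask(m, path)
    expect_identical(as.matrix(read_mask(path)), as.matrix(m))
  }
})

test_that("regularity report keeps missing tumors as NA rows", {
  circ <- generate_tumor_mask("circle", size_px = 96, r = 30)
  masks <- c(rep(list(circ), 4), list(NULL, NA), rep(list(circ), 4))
  rep10 <- regularity_report(masks, rep("PDC", 10))
  expect_equal(nrow(rep10), 10L)
  expect_equal(sum(is.na(rep10$f_value)), 2L)
  summ <- regularity_summary(rep10)
  expect_equal(summ$n, 8L)
  expect_equal(summ$n_missing, 2L)
  expect_equal(summ$sd_f, 0)  # identical circles
})

test_that("circle and elongated-ellipse groups separate in F at n = 8", {
  masks <- c(
    purrr::map(1:8, ~generate_tumor_mask("perturbed_blob", size_px = 96,
                                         r = 30, perturbation = 0.03,
                                         seed = .x)),
    purrr::map(1:8, ~generate_tumor_mask("ellipse", size_px = 96,
                                         a = 28 + .x, b = (28 + .x) / 2))
  )
  rep2 <- regularity_report(masks, rep(c("regular", "elongated"), each = 8))
  cmp <- compare_groups(rep2, f_value, group)
  expect_true(all(cmp$pairwise$significant))
  # half-ellipses sit near F = 0.5, near-circular blobs near 0
  diff_f <- abs(diff(regularity_summary(rep2)$mean_f))
  expect_gt(diff_f, 0.38)
  expect_lt(diff_f, 0.55)
})
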