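test_that("contour metrics match hand-computed area and perimeter", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  m <- contour_metrics(sq)
  expect_equal(m$A, 1)
  expect_equal(m$C, 4)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  m2 <- contour_metrics(tri)
  expect_equal(m2$A, 6)
  expect_equal(m2$C, 12)
  expect_error(contour_metrics(rbind(c(0, 0), c(1, 1))), "3 vertices")
  expect_error(contour_metrics(rbind(c(0, 0), c(1, 1), c(2, 2))), "area")
})

test_that("polyline length sums Euclidean steps", {
  expect_equal(polyline_length(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(polyline_length(rbind(c(0, 0), c(1, 0), c(1, 1))), 2)
  expect_error(polyline_length(rbind(c(0, 0))), "2 vertices")
})

test_that("rectangle-equivalent estimator inverts rectangles and clamps round contours", {
  r <- rect_equivalent(1, 4)
  expect_equal(r$L, 1); expect_equal(r$D, 1); expect_false(r$clamped)
  r2 <- rect_equivalent(5, 12)  # 5 x 1 rectangle
  expect_equal(r2$L, 5); expect_equal(r2$D, 1)
  # unit circle: C^2 = 4 pi^2 < 16 pi, no rectangle exists
  expect_warning(r3 <- rect_equivalent(pi, 2 * pi), "clamp")
  expect_true(r3$clamped)
  expect_equal(r3$L, pi / 2); expect_equal(r3$D, pi / 2)
  expect_error(rect_equivalent(-1, 4), "positive")
})

test_that("rectangle inversion identities hold on random rectangles", {
  set.seed(101)
  for (i in 1:200) {
    D <- runif(1, 0.05, 3)
    L <- D + runif(1, 0, 10)
    r <- rect_equivalent(L * D, 2 * (L + D))
    expect_false(r$clamped)
    expect_equal(r$L, L, tolerance = 1e-9)
    expect_equal(r$D, D, tolerance = 1e-9)
    expect_equal(r$L * r$D, r$A, tolerance = 1e-9)
    expect_equal(r$L + r$D, r$C / 2, tolerance = 1e-9)
    expect_gte(r$L, r$D)
  }
})

test_that("clamping occurs exactly when C^2 < 16A", {
  set.seed(102)
  for (i in 1:100) {
    A <- runif(1, 0.1, 20); C <- runif(1, 1, 25)
    if (C^2 >= 16 * A) {
      r <- rect_equivalent(A, C)
      expect_false(r$clamped)
    } else {
      expect_warning(r <- rect_equivalent(A, C))
      expect_true(r$clamped)
      expect_equal(r$L, C / 4)
    }
  }
})

test_that("union-of-polygons area counts overlaps once and respects clipping", {
  r1 <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1))
  r2 <- rbind(c(1, 0), c(3, 0), c(3, 1), c(1, 1))
  expect_equal(poly_union_area(list(r1, r2)), 3, tolerance = 1e-12)
  expect_equal(poly_intersect_area(r1, r2), 1, tolerance = 1e-12)
  clip <- rbind(c(0.5, -1), c(2.5, -1), c(2.5, 2), c(0.5, 2))
  expect_equal(poly_union_area(list(r1, r2), clip), 2, tolerance = 1e-12)
  # rotated overlapping squares: hand-computable cross shape
  a <- rbind(c(-2, -0.5), c(2, -0.5), c(2, 0.5), c(-2, 0.5))
  b <- rbind(c(-0.5, -2), c(0.5, -2), c(0.5, 2), c(-0.5, 2))
  expect_equal(poly_union_area(list(a, b)), 4 + 4 - 1, tolerance = 1e-12)
})

test_that("specimen morphometry reproduces a constructed block example", {
  spec <- block_specimen()
  m <- specimen_morphometry(spec)
  expect_equal(m$CTI_A, 100)
  expect_equal(m$CTI_m, 2, tolerance = 1e-12)
  expect_equal(m$CTI_nm, 78, tolerance = 1e-12)  # 100 - 2 - 10 (TC) - 10 (VB)
  expect_equal(m$CTI_nm_ratio, 39, tolerance = 1e-12)
  expect_equal(m$ILI_L, 10); expect_equal(m$CI_L, 10); expect_equal(m$PSI_L, 10)
  expect_equal(m$ratio_CI_ILI, 1)
  # TC strip is a 10 x 1 rectangle
  expect_equal(m$TC_A, 10); expect_equal(m$TC_L, 10, tolerance = 1e-9)
  expect_equal(m$TC_D, 1, tolerance = 1e-9)
})

test_that("trapezoid ratios are the plain isthmus-length quotients", {
  b <- square_boundary()
  b$corners$cC <- c(5, 7.5); b$corners$psC <- c(10, 3.75)
  b$ci_line <- rbind(c(5, 0), c(5, 7.5))
  b$psi_line <- rbind(c(10, 0), c(10, 3.75))
  b$cti_boundary <- rbind(c(0, 0), c(5, 0), c(10, 0), c(10, 3.75), c(5, 7.5), c(0, 10))
  b$tc_contour <- rbind(c(0, 10), c(5, 7.5), c(10, 3.75), c(10, 3), c(5, 6.7), c(0, 9.2))
  rams <- rbind(ram_row("c1", "c", 1, 2, 7), ram_row("v1", "v", 1, 2, 1.5))
  segs <- seg_row("P.c1.v1", "c1", "v1", rect_between(c(2, 7), c(2, 1.5), 0.5))
  spec <- new_cti_specimen("TRAP", resolution = 10, corners = b$corners,
                           tc_contour = b$tc_contour, vb_contour = b$vb_contour,
                           ili_line = b$ili_line, ci_line = b$ci_line,
                           psi_line = b$psi_line, cti_boundary = b$cti_boundary,
                           ramifications = rams, segments = segs)
  m <- specimen_morphometry(spec)
  expect_equal(m$ILI_L, 10); expect_equal(m$CI_L, 7.5); expect_equal(m$PSI_L, 3.75)
  expect_equal(m$ratio_CI_ILI, 0.75)
  expect_equal(m$ratio_PSI_CI, 0.5)
  expect_equal(m$ratio_PSI_ILI, 0.375)
})

test_that("morphometry reports missing ratio when no segments are included", {
  spec <- block_specimen()
  spec$segments <- spec$segments[0, ]
  expect_warning(m <- specimen_morphometry(spec, spec$segments), "CTI_m = 0")
  expect_equal(m$CTI_m, 0)
  expect_true(is.na(m$CTI_nm_ratio))
})

test_that("morphometry is invariant under rigid motions", {
  spec <- block_specimen()
  m0 <- specimen_morphometry(spec)
  set.seed(103)
  for (i in 1:5) {
    sp2 <- transform_specimen(spec, runif(1, 0, 2 * pi), runif(1, -30, 30),
                              runif(1, -30, 30))
    m1 <- specimen_morphometry(sp2)
    for (col in setdiff(names(m0), "specimen_id"))
      expect_equal(m1[[col]], m0[[col]], tolerance = 1e-9, label = col)
  }
})
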