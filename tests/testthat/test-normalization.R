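test_that("identity layout yields the identity coefficients", {
  map <- fit_bilinear(identity_corners())
  expect_equal(map$left$alpha, c(0, 1, 0, 0), tolerance = 1e-12)
  expect_equal(map$left$beta, c(0, 0, 1, 0), tolerance = 1e-12)
  expect_equal(map$right$alpha, c(0, 1, 0, 0), tolerance = 1e-12)
  # doubling all corners doubles the linear coefficients
  map2 <- fit_bilinear(lapply(identity_corners(), function(p) 2 * p))
  expect_equal(map2$left$alpha, c(0, 2, 0, 0), tolerance = 1e-12)
  expect_equal(map2$left$beta, c(0, 0, 2, 0), tolerance = 1e-12)
})

test_that("the left-half solve matrix has the known closed form", {
  expected <- rbind(c(1, 0, 0, 0), c(-2, 2, 0, 0), c(-1, 0, 0, 1),
                    c(2, -2, 2, -2))
  expect_equal(unname(bilinear_solve_matrix("left")), expected, tolerance = 1e-12)
  # it is layout-independent: any corner set is solved through the same matrix
  set.seed(201)
  cc <- random_layout()
  map <- fit_bilinear(cc)
  xs <- vapply(c("ilV", "cV", "cC", "ilC"), function(n) cc[[n]][1], numeric(1))
  expect_equal(map$left$alpha, as.numeric(expected %*% xs), tolerance = 1e-9)
})

test_that("collinear corners give a degenerate-quad error", {
  cc <- identity_corners()
  cc$ilC <- cc$ilV  # collapses the left quadrilateral
  expect_error(fit_bilinear(cc), "degenerate")
})

test_that("corners map exactly to their prescribed normalized positions", {
  set.seed(202)
  lm_of <- list(ilV = c(0, 0), cV = c(0.5, 0), cC = c(0.5, 1),
                ilC = c(0, 1), psV = c(1, 0), psC = c(1, 1))
  for (rep in 1:20) {
    cc <- random_layout()
    map <- fit_bilinear(cc)
    scale <- max(abs(unlist(cc)))
    for (nm in names(lm_of)) {
      img <- to_image(map, lm_of[[nm]][1], lm_of[[nm]][2])
      expect_lt(max(abs(img - cc[[nm]])), 1e-12 * scale)
      inv <- to_normalized(map, cc[[nm]][1], cc[[nm]][2])
      expect_lt(max(abs(c(inv$l, inv$m) - lm_of[[nm]])), 1e-9)
    }
  }
})

test_that("the two patches agree along the central isthmus edge", {
  set.seed(203)
  for (rep in 1:20) {
    map <- fit_bilinear(random_layout())
    m <- seq(0, 1, length.out = 100)
    left <- cbind(map$left$alpha[1] + map$left$alpha[2] * 0.5 + map$left$alpha[3] * m +
                    map$left$alpha[4] * 0.5 * m,
                  map$left$beta[1] + map$left$beta[2] * 0.5 + map$left$beta[3] * m +
                    map$left$beta[4] * 0.5 * m)
    right <- to_image(map, rep(0.500000001, 100), m)  # just inside the right patch
    expect_lt(max(abs(left - right)), 1e-6)
    expect_lt(max(abs(left - to_image(map, rep(0.5, 100), m))), 1e-9)
  }
})

test_that("forward-then-inverse recovers interior points to 1e-9 mm", {
  set.seed(204)
  for (rep in 1:20) {
    map <- fit_bilinear(random_layout())
    l <- runif(25); m <- runif(25)
    img <- to_image(map, l, m)
    inv <- to_normalized(map, img[, 1], img[, 2])
    back <- to_image(map, inv$l, inv$m)
    expect_lt(max(abs(back - img)), 1e-9)
    expect_lt(max(abs(inv$l - l)), 1e-7)
    expect_lt(max(abs(inv$m - m)), 1e-7)
  }
})

test_that("parallelogram patches use the exact linear (affine) inverse", {
  # both halves parallelograms: bilinear terms vanish, quadratic degenerates
  cc <- list(ilV = c(0, 0), cV = c(5, 1), psV = c(10, 2),
             ilC = c(2, 8), cC = c(7, 9), psC = c(12, 10))
  map <- fit_bilinear(cc)
  expect_equal(map$left$alpha[4], 0, tolerance = 1e-12)
  expect_equal(map$left$beta[4], 0, tolerance = 1e-12)
  # closed-form affine inverse of the left patch
  A <- cbind(map$left$alpha[2:3], map$left$beta[2:3])
  set.seed(205)
  pts <- cbind(runif(20, 0, 0.5), runif(20))
  img <- to_image(map, pts[, 1], pts[, 2])
  inv <- to_normalized(map, img[, 1], img[, 2])
  for (i in 1:20) {
    lm_exact <- solve(t(A), c(img[i, 1] - map$left$alpha[1],
                              img[i, 2] - map$left$beta[1]))
    expect_equal(c(inv$l[i], inv$m[i]), unname(lm_exact), tolerance = 1e-9)
  }
})

test_that("points beyond the TC chord map above the unit square", {
  map <- fit_bilinear(identity_corners())
  res <- to_normalized(map, 0.25, 1.2)
  expect_equal(res$l, 0.25, tolerance = 1e-9)
  expect_equal(res$m, 1.2, tolerance = 1e-9)
  expect_gt(res$m, 1)
})

test_that("normalize_specimen maps every ramification including virtual anchors", {
  g <- generate_specimen(seed = 21)
  np <- normalize_specimen(g$specimen)
  expect_equal(nrow(np), nrow(g$specimen$ramifications))
  expect_true(all(is.finite(np$l)))
  ord <- match(np$id, g$truth$normalized$id)
  expect_lt(max(abs(np$l - g$truth$normalized$l[ord])), 1e-9)
  expect_lt(max(abs(np$m - g$truth$normalized$m[ord])), 1e-9)
  # corner psV maps to (1, 0)
  res <- to_normalized(fit_bilinear(g$specimen$corners),
                       g$specimen$corners$psV[1], g$specimen$corners$psV[2])
  expect_equal(c(res$l, res$m), c(1, 0), tolerance = 1e-9)
})
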