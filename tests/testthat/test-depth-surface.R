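test_that("pixel indices map to centered image-plane coordinates", {
  expect_equal(imageToPlaneCoords(2, 2, 5, 5), list(xb = 0, ya = 0))
  expect_equal(imageToPlaneCoords(0, 0, 5, 5), list(xb = -2, ya = 2))
  expect_equal(imageToPlaneCoords(0, 0, 4, 4), list(xb = -1.5, ya = 1.5))
  expect_error(imageToPlaneCoords(5, 0, 5, 5), "row index")
  expect_error(imageToPlaneCoords(0, -1, 5, 5), "column index")
})

test_that("coordinate mapping is affine and exactly invertible", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:40, 1); m <- sample(2:40, 1)
    ## dyadic sub-pixel queries, where float subtraction is exact
    a <- sample(0:(8 * (n - 1)), 5) / 8
    b <- sample(0:(8 * (m - 1)), 5) / 8
    pc <- imageToPlaneCoords(a, b, n, m)
    back <- planeToImageCoords(pc$xb, pc$ya, n, m)
    expect_identical(back$a, a)
    expect_identical(back$b, b)
  }
})

test_that("patch evaluation matches the printed polynomial family", {
  expect_equal(evalPatch(SurfacePatch(1, c(1, 2, 3)), 1, 1), 6)
  q <- SurfacePatch(5, c(rep(0, 14), 1))      # only the y^4 term
  expect_equal(evalPatch(q, 1, 2), 16)
  set.seed(7)
  patch <- random_patch(4)
  x <- runif(100, -3, 3); y <- runif(100, -3, 3)
  expect_equal(evalPatch(patch, x, y),
               oracle_eval_patch(4, patchCoeffs(patch), x, y),
               tolerance = 1e-12)
})

test_that("coefficient count must match the tier", {
  expect_error(SurfacePatch(1, c(1, 2)), "3 coefficients")
  expect_error(SurfacePatch(3, rep(0, 5)), "6 coefficients")
  expect_error(SurfacePatch(6, rep(0, 3)), "tier")
})

test_that("zero-padding a patch to a higher tier changes no value", {
  set.seed(21)
  counts <- c(3, 4, 6, 10, 15)
  for (t in 2:5) {
    lower <- random_patch(t - 1)
    padded <- SurfacePatch(t, c(patchCoeffs(lower),
                                rep(0, counts[t] - counts[t - 1])))
    x <- runif(30, -2, 2); y <- runif(30, -2, 2)
    expect_equal(evalPatch(padded, x, y), evalPatch(lower, x, y),
                 tolerance = 1e-14)
  }
})

test_that("the plane through three points reproduces their depths", {
  expect_equal(patchCoeffs(fitPlaneFromPoints(c(0, 0, 5), c(1, 0, 5),
                                              c(0, 1, 5))),
               c(5, 0, 0))
  expect_equal(patchCoeffs(fitPlaneFromPoints(c(0, 0, 0), c(1, 0, 1),
                                              c(0, 1, 2))),
               c(0, 1, 2))
  set.seed(5)
  for (i in 1:20) {
    P <- matrix(runif(9, -5, 5), 3)
    ## reject near-collinear draws so the exactness claim is well-posed
    if (abs(det(cbind(1, P[, 1], P[, 2]))) < 1e-2) next
    patch <- fitPlaneFromPoints(P[1, ], P[2, ], P[3, ])
    expect_equal(evalPatch(patch, P[, 1], P[, 2]), P[, 3],
                 tolerance = 1e-10)
  }
})

test_that("collinear points are rejected as degenerate geometry", {
  expect_error(fitPlaneFromPoints(c(0, 0, 1), c(1, 1, 2), c(2, 2, 3)),
               "degenerate geometry")
  expect_error(fitPlaneFromPoints(c(1, 1, 0), c(1, 1, 1), c(2, 2, 3)),
               "degenerate geometry")
})

test_that("triangular depth interpolation reproduces vertices and ramps", {
  set.seed(3)
  d <- matrix(runif(48, 0, 10), 6, 8)
  img <- DepthImage(d)
  expect_identical(interpolateDepth(img, 3, 4), d[4, 5])
  ramp <- DepthImage(outer(0:7, rep(1, 5)))    # depth equals the row index
  expect_equal(interpolateDepth(ramp, 1.5, 0.25), 1.5)
})

test_that("triangular interpolation matches a barycentric-solve oracle", {
  set.seed(42)
  d <- matrix(runif(64, -5, 5), 8, 8)
  img <- DepthImage(d)
  a <- runif(50, 0, 7); b <- runif(50, 0, 7)
  got <- interpolateDepth(img, a, b)
  for (i in 1:50) {
    a0 <- min(floor(a[i]), 6); b0 <- min(floor(b[i]), 6)
    u <- a[i] - a0; v <- b[i] - b0
    ## the quad is split along its (a0,b0)-(a0+1,b0+1) diagonal
    tri <- if (u >= v)
      cbind(c(0, 0), c(1, 1), c(1, 0))
    else
      cbind(c(0, 0), c(1, 1), c(0, 1))
    z <- apply(tri, 2, function(t) d[a0 + t[1] + 1, b0 + t[2] + 1])
    expect_equal(got[i], oracle_barycentric(t(tri), z, c(u, v)),
                 tolerance = 1e-12)
  }
})

test_that("interpolation is exact on a global plane for either triangle", {
  set.seed(9)
  n <- 7; m <- 9
  a <- matrix(rep(0:(n - 1), m), n)
  b <- matrix(rep(0:(m - 1), each = n), n)
  img <- DepthImage(3 - 0.5 * a + 1.25 * b)
  qa <- runif(40, 0, n - 1); qb <- runif(40, 0, m - 1)
  expect_equal(interpolateDepth(img, qa, qb), 3 - 0.5 * qa + 1.25 * qb,
               tolerance = 1e-12)
})

test_that("masked or out-of-grid queries are refused", {
  d <- matrix(1:9 + 0, 3, 3)
  mask <- matrix(TRUE, 3, 3); mask[2, 2] <- FALSE
  img <- DepthImage(d, mask)
  expect_error(interpolateDepth(img, 0.5, 0.5), "masked")
  expect_error(interpolateDepth(img, 2.5, 0.5), "out of range")
  expect_equal(interpolateDepth(DepthImage(d), 0.5, 0.5),
               interpolateDepth(DepthImage(d), 0.5, 0.5))
})
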