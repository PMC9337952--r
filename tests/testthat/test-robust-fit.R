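scatter_on_patch <- function(n, patch, noise = 0, seed = 1) {
  set.seed(seed)
  x <- runif(n, -2, 2); y <- runif(n, -2, 2)
  z <- evalPatch(patch, x, y) + rnorm(n, sd = noise)
  cbind(x = x, y = y, z = z)
}

test_that("chi-square is the brute-force sum of squared residuals", {
  patch <- SurfacePatch(1, c(1, 0, 0))
  on_patch <- cbind(x = runif(10), y = runif(10), z = 1)
  expect_equal(chiSquare(patch, on_patch), 0)
  expect_equal(chiSquare(patch, cbind(0, 0, 3)), 4)   # residual 2
  set.seed(13)
  patch <- random_patch(3)
  pts <- scatter_on_patch(40, random_patch(2), noise = 1, seed = 14)
  acc <- 0
  for (i in seq_len(nrow(pts)))
    acc <- acc + (pts[i, 3] -
                    oracle_eval_patch(3, patchCoeffs(patch),
                                      pts[i, 1], pts[i, 2]))^2
  expect_equal(chiSquare(patch, pts), unname(acc), tolerance = 1e-10)
})

test_that("least squares recovers generating coefficients from noiseless data", {
  set.seed(2)
  truth <- random_patch(3)
  pts <- scatter_on_patch(60, truth, seed = 3)
  fit <- leastSquaresFit(pts, 3)
  expect_equal(patchCoeffs(fittedPatch(fit)), patchCoeffs(truth),
               tolerance = 1e-9)
  expect_lt(fitChiSquare(fit), 1e-18)
})

test_that("constant data yields the constant patch at any tier", {
  set.seed(4)
  pts <- cbind(x = runif(30, -1, 1), y = runif(30, -1, 1), z = 7)
  for (tier in c(1, 3)) {
    co <- patchCoeffs(fittedPatch(leastSquaresFit(pts, tier)))
    expect_equal(co[1], 7, tolerance = 1e-10)
    expect_equal(co[-1], rep(0, length(co) - 1), tolerance = 1e-10)
  }
})

test_that("underdetermined and rank-deficient designs are refused", {
  pts4 <- cbind(x = runif(4), y = runif(4), z = runif(4))
  expect_error(leastSquaresFit(pts4, 3), "insufficient data")
  ## many points but all on a line in (x, y): plane is not identifiable
  line <- cbind(x = 1:10, y = 2 * (1:10), z = runif(10))
  expect_error(leastSquaresFit(line, 1), "degenerate design")
})

test_that("stored fit statistics are recomputable from the patch", {
  set.seed(6)
  pts <- scatter_on_patch(50, random_patch(2), noise = 0.4, seed = 7)
  for (fit in list(leastSquaresFit(pts, 2),
                   lmedsFit(pts, 2, nSubsets = 100, seed = 1),
                   regularizedFit(pts, 3, alpha = 0.5))) {
    expect_equal(fitChiSquare(fit), chiSquare(fittedPatch(fit), pts),
                 tolerance = 1e-10)
    r2 <- (pts[, 3] - evalPatch(fittedPatch(fit), pts[, 1], pts[, 2]))^2
    expect_equal(medianSqResidual(fit), oracle_lower_median(r2),
                 tolerance = 1e-12)
  }
})

test_that("LMedS matches exhaustive minimal-subset enumeration on 14 points", {
  set.seed(8)
  pts <- rbind(
    cbind(x = runif(10, -1, 1), y = runif(10, -1, 1), z = 0),
    cbind(x = runif(4, -1, 1), y = runif(4, -1, 1), z = 100))
  oracle <- oracle_lmeds_plane(pts)
  fit <- lmedsFit(pts, 1, nSubsets = 500, seed = 9, refine = FALSE)
  expect_equal(medianSqResidual(fit), oracle$median, tolerance = 1e-12)
  expect_equal(patchCoeffs(fittedPatch(fit)), unname(oracle$coeffs),
               tolerance = 1e-6)
  expect_lt(medianSqResidual(fit), 1e-12)
  refined <- lmedsFit(pts, 1, nSubsets = 500, seed = 9)
  expect_equal(patchCoeffs(fittedPatch(refined)), c(0, 0, 0),
               tolerance = 1e-6)
})

test_that("LMedS is deterministic per seed and exact on clean planes", {
  set.seed(10)
  pts <- scatter_on_patch(30, SurfacePatch(1, c(2, -1, 0.5)), seed = 11)
  f1 <- lmedsFit(pts, 1, nSubsets = 200, seed = 5)
  f2 <- lmedsFit(pts, 1, nSubsets = 200, seed = 5)
  expect_identical(patchCoeffs(fittedPatch(f1)), patchCoeffs(fittedPatch(f2)))
  expect_identical(fitChiSquare(f1), fitChiSquare(f2))
  expect_identical(inlierMask(f1), inlierMask(f2))
  expect_equal(medianSqResidual(f1), 0, tolerance = 1e-18)
  expect_equal(patchCoeffs(fittedPatch(f1)), c(2, -1, 0.5),
               tolerance = 1e-9)
})

test_that("LMedS with refinement agrees with least squares on outlier-free data", {
  set.seed(12)
  pts <- scatter_on_patch(80, SurfacePatch(1, c(1, 0.3, -0.7)), seed = 13)
  ls <- leastSquaresFit(pts, 1)
  rob <- lmedsFit(pts, 1, nSubsets = 500, seed = 3)
  expect_equal(patchCoeffs(fittedPatch(rob)), patchCoeffs(fittedPatch(ls)),
               tolerance = 1e-6)
})

test_that("LMedS survives 30% gross outliers (breakdown property)", {
  truth <- SurfacePatch(1, c(5, 1.5, -2))
  for (seed in 1:5) {
    pts <- scatter_on_patch(50, truth, seed = seed)
    set.seed(seed + 100)
    bad <- sample(50, 15)                       # exactly 30%
    pts[bad, 3] <- pts[bad, 3] + 200
    fit <- lmedsFit(pts, 1, nSubsets = 500, seed = seed)
    r2true <- (pts[, 3] - evalPatch(truth, pts[, 1], pts[, 2]))^2
    expect_lte(medianSqResidual(fit), oracle_lower_median(r2true) + 1e-9)
    expect_equal(patchCoeffs(fittedPatch(fit)), patchCoeffs(truth),
                 tolerance = 1e-6)
  }
})

test_that("LMedS requires at least a minimal subset of points", {
  pts <- cbind(x = runif(2), y = runif(2), z = runif(2))
  expect_error(lmedsFit(pts, 1), "insufficient data")
})

test_that("regularization reduces to least squares at alpha = 0", {
  set.seed(20)
  pts <- scatter_on_patch(40, random_patch(3), noise = 0.2, seed = 21)
  r0 <- regularizedFit(pts, 3, alpha = 0)
  ls <- leastSquaresFit(pts, 3)
  expect_equal(patchCoeffs(fittedPatch(r0)), patchCoeffs(fittedPatch(ls)),
               tolerance = 1e-8)
  expect_error(regularizedFit(pts, 3, alpha = -1), "non-negative")
})

test_that("heavy smoothing drives the fit to the best affine surface", {
  set.seed(22)
  truth <- SurfacePatch(3, c(1, 0.5, -0.25, 0.8, 1.2, -0.6))
  pts <- scatter_on_patch(60, truth, seed = 23)
  heavy <- regularizedFit(pts, 3, alpha = 1e8)
  co <- patchCoeffs(fittedPatch(heavy))
  expect_equal(co[4:6], rep(0, 3), tolerance = 1e-8)   # curvature terms die
  plane <- leastSquaresFit(pts, 1)
  expect_equal(co[1:3], patchCoeffs(fittedPatch(plane)), tolerance = 1e-4)
})

test_that("chi-square is non-decreasing in the smoothing weight", {
  set.seed(24)
  pts <- scatter_on_patch(60, random_patch(3), noise = 0.3, seed = 25)
  chis <- vapply(c(0, 0.1, 1, 10), function(a)
    fitChiSquare(regularizedFit(pts, 3, alpha = a)), numeric(1))
  expect_true(all(diff(chis) >= -1e-9))
})

test_that("the penalized solution is unique for alpha > 0", {
  ## three non-collinear points under-determine a quadratic patch, yet the
  ## penalty makes the solution unique and reproducible
  pts <- cbind(x = c(0, 1, 0), y = c(0, 0, 1), z = c(1, 2, 3))
  f1 <- regularizedFit(pts, 3, alpha = 0.7)
  f2 <- regularizedFit(pts, 3, alpha = 0.7)
  expect_identical(patchCoeffs(fittedPatch(f1)), patchCoeffs(fittedPatch(f2)))
  expect_true(all(is.finite(patchCoeffs(fittedPatch(f1)))))
})
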