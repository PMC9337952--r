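rand_image <- function(n, seed, mx = 255) {
  set.seed(seed)
  matrix(runif(n * n, 0, mx), n)
}

test_that("MSE matches its double-loop definition and is symmetric", {
  I <- rand_image(16, 51)
  expect_equal(mse(ImagePair(I, I)), 0)
  expect_equal(mse(ImagePair(matrix(0), matrix(2), 255)), 4)
  K <- rand_image(16, 52)
  expect_equal(mse(ImagePair(I, K)), oracle_mse(I, K), tolerance = 1e-10)
  expect_identical(mse(ImagePair(I, K)), mse(ImagePair(K, I)))
  expect_error(ImagePair(I, rand_image(8, 53)), "dimension mismatch")
})

test_that("PSNR follows its closed form and the identical-image sentinel", {
  I <- rand_image(16, 54)
  expect_identical(psnr(ImagePair(I, I)), Inf)
  ## MAX_I = 255, MSE = 1: PSNR = 20 log10(255)
  I0 <- matrix(100, 4, 4); K0 <- matrix(101, 4, 4)
  expect_equal(psnr(ImagePair(I0, K0)), 20 * log10(255), tolerance = 1e-12)
  ## doubling MSE lowers PSNR by exactly 10 log10(2) dB
  K1 <- I0 + sqrt(2)
  expect_equal(psnr(ImagePair(I0, K0)) - psnr(ImagePair(I0, K1)),
               10 * log10(2), tolerance = 1e-9)
  ## strictly decreasing in MSE at fixed MAX_I
  psnrs <- vapply(c(0.5, 1, 2, 5), function(d)
    psnr(ImagePair(I0, I0 + d)), numeric(1))
  expect_true(all(diff(psnrs) < 0))
})

test_that("PSNR bands reproduce the printed decibel thresholds", {
  expect_identical(psnrBand(45), "excellent")
  expect_identical(psnrBand(35.216), "good")
  expect_identical(psnrBand(19.99), "unacceptable")
  expect_identical(psnrBand(Inf), "excellent")
  ## boundary ties: excellent needs strictly more than 40 dB
  expect_identical(psnrBand(c(40, 30, 20)), c("good", "good", "poor"))
  expect_identical(psnrBand(40 + 1e-9), "excellent")
  expect_identical(psnrBand(30 - 1e-9), "poor")
  expect_identical(psnrBand(20 - 1e-9), "unacceptable")
  expect_error(psnrBand(-1), "non-negative")
})

test_that("SSIM of an image with itself is exactly 1", {
  for (seed in 1:5) {
    I <- rand_image(64, seed)
    expect_identical(ssim(ImagePair(I, I)), 1)
  }
})

test_that("SSIM is symmetric and orders distortions sensibly", {
  I <- rand_image(32, 60)
  offset <- ImagePair(I, pmin(I + 10, 255))
  inverted <- ImagePair(I, 255 - I)
  sOff <- ssim(offset)
  sInv <- ssim(inverted)
  expect_lt(sOff, 1)
  expect_gt(sOff, sInv)     # structure-preserving beats structure-inverting
  swapped <- ImagePair(pmin(I + 10, 255), I)
  expect_equal(ssim(offset), ssim(swapped), tolerance = 1e-12)
})

test_that("single-window SSIM matches a brute-force windowed computation", {
  ## an 11x11 pair has exactly one window position; uniform weights make
  ## the hand computation transparent
  set.seed(61)
  I <- matrix(runif(121, 0, 255), 11)
  K <- pmin(pmax(I + rnorm(121, 0, 20), 0), 255)
  w <- rep(1 / 121, 121)
  ux <- sum(w * I); uy <- sum(w * K)
  vx <- sum(w * I^2) - ux^2; vy <- sum(w * K^2) - uy^2
  cxy <- sum(w * I * K) - ux * uy
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2; c3 <- c2 / 2
  l <- (2 * ux * uy + c1) / (ux^2 + uy^2 + c1)
  cc <- (2 * sqrt(vx) * sqrt(vy) + c2) / (vx + vy + c2)
  ss <- (cxy + c3) / (sqrt(vx) * sqrt(vy) + c3)
  got <- ssim(ImagePair(I, K), windowSize = 11, gaussianSigma = 1e8)
  expect_equal(got, l * cc * ss, tolerance = 1e-9)
})

test_that("SSIM with equal exponents never exceeds 1 and flags size errors", {
  for (seed in 1:5) {
    I <- rand_image(24, seed + 70)
    K <- rand_image(24, seed + 80)
    expect_lte(ssim(ImagePair(I, K)), 1)
  }
  small <- rand_image(8, 90)
  expect_error(ssim(ImagePair(small, small)), "smaller than")
  expect_error(ssim(ImagePair(small, small), windowSize = 4),
               "odd")
})

test_that("VAS scores band into the printed discomfort categories", {
  expect_identical(vasBand(1), "comfortable")
  expect_identical(vasBand(7), "severe discomfort")
  expect_error(vasBand(11), "\\[0, 10\\]")
  expect_error(vasBand(-0.5), "\\[0, 10\\]")
  expect_identical(vasBand(c(0, 2, 3, 4, 5, 6, 8, 9, 10)),
                   c("comfortable", "comfortable", "mild discomfort",
                     "mild discomfort", "moderate discomfort",
                     "moderate discomfort", "severe discomfort",
                     "extreme discomfort", "extreme discomfort"))
})

test_that("algorithm comparison reports recompute and preserve order", {
  I <- rand_image(48, 95)
  low <- makeSpecklePair(I, 0.05, seed = 1)
  high <- makeSpecklePair(I, 0.3, seed = 1)
  rep <- compareAlgorithms(I, list(self = I, low = testImage(low),
                                   high = testImage(high)))
  tab <- reportTable(rep)
  expect_identical(tab$algorithm, c("self", "low", "high"))
  expect_identical(tab$psnr_db[1], Inf)
  expect_identical(tab$psnr_band[1], "excellent")
  expect_identical(tab$ssim[1], 1)
  ## noisier input scores strictly worse on both metrics
  expect_gt(tab$psnr_db[2], tab$psnr_db[3])
  expect_gt(tab$ssim[2], tab$ssim[3])
  ## every cell is reproducible from the stored inputs
  expect_equal(tab$psnr_db[3], psnr(high), tolerance = 1e-9)
  expect_equal(tab$ssim[3], ssim(high), tolerance = 1e-9)
})

test_that("an empty comparison yields an empty report without error", {
  rep <- compareAlgorithms(rand_image(16, 99), list())
  expect_identical(nrow(reportTable(rep)), 0L)
  expect_error(compareAlgorithms(rand_image(16, 99),
                                 list(bad = rand_image(8, 98))),
               "bad")
})
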