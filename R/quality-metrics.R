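#' @include AllClasses.R
NULL

#' Mean squared error of an image pair
#'
#' \deqn{\mathrm{MSE} = \frac{1}{mn} \sum_{i=0}^{m-1} \sum_{j=0}^{n-1}
#'       (I_{ij} - K_{ij})^2}
#' over the two m x n monochrome images of the pair.
#'
#' @param pair an [ImagePair-class].
#' @return A single non-negative number; 0 iff the images are identical.
#' @export
mse <- function(pair) {
  stopifnot(is(pair, "ImagePair"))
  d <- pair@reference - pair@test
  sum(d * d) / length(d)
}

#' Peak signal-to-noise ratio in decibels
#'
#' \deqn{\mathrm{PSNR} = 10 \log_{10}\!\frac{\mathrm{MAX}_I^2}{\mathrm{MSE}}
#'      = 20 \log_{10}\!\frac{\mathrm{MAX}_I}{\sqrt{\mathrm{MSE}}}.}
#' For identical images (MSE = 0) the formula is undefined; the
#' distinguished sentinel `Inf` is returned rather than a division failure,
#' and [psnrBand()] maps it to `"excellent"`.
#'
#' @param pair an [ImagePair-class].
#' @return PSNR in dB, or `Inf` for identical images.
#' @export
psnr <- function(pair) {
  m <- mse(pair)
  if (m == 0) return(Inf)
  10 * log10(pair@maxIntensity^2 / m)
}

#' PSNR quality band
#'
#' Maps a PSNR value (dB) to the conventional ultrasound image-quality
#' bands: above 40 dB the reconstruction is excellent (very close to the
#' original), 30-40 dB good (distortion perceptible but acceptable),
#' 20-30 dB poor, and below 20 dB unacceptable. Boundary ties: 40 dB and
#' 30 dB are "good" (excellent requires strictly more than 40 dB), 20 dB
#' is "poor". The `Inf` sentinel for identical images is "excellent".
#'
#' @param psnrDb non-negative PSNR in dB (vectorized), or `Inf`.
#' @return Character vector of band labels in
#'   `{"excellent", "good", "poor", "unacceptable"}`.
#' @examples
#' psnrBand(c(45, 35.216, 19.99))
#' @export
psnrBand <- function(psnrDb) {
  if (any(is.na(psnrDb)) || any(psnrDb < 0))
    stop("PSNR must be non-negative (dB)")
  ifelse(psnrDb > 40, "excellent",
         ifelse(psnrDb >= 30, "good",
                ifelse(psnrDb >= 20, "poor", "unacceptable")))
}

## Valid (no-padding) separable correlation of image M with a 1D kernel k
## applied along rows then columns, via banded convolution matrices.
.convBand <- function(size, k) {
  w <- length(k)
  out <- matrix(0, size - w + 1L, size)
  for (i in seq_len(size - w + 1L)) out[i, i:(i + w - 1L)] <- k
  out
}

.filterValid <- function(M, k) {
  A <- .convBand(nrow(M), k)
  B <- .convBand(ncol(M), k)
  A %*% M %*% t(B)
}

#' Structural similarity index (SSIM)
#'
#' Computes the structural similarity of the pair's two images as the mean
#' over all local window positions of
#' \deqn{l(x,y)^\alpha \, c(x,y)^\beta \, s(x,y)^\gamma,}
#' where \eqn{l}, \eqn{c} and \eqn{s} compare local luminance, contrast and
#' structure through Gaussian-weighted window means \eqn{\mu},
#' standard deviations \eqn{\sigma} and covariance \eqn{\sigma_{xy}} with
#' stabilization constants \eqn{C_1, C_2, C_3}:
#' \deqn{l = \frac{2\mu_x\mu_y + C_1}{\mu_x^2 + \mu_y^2 + C_1},\quad
#'       c = \frac{2\sigma_x\sigma_y + C_2}{\sigma_x^2 + \sigma_y^2 + C_2},\quad
#'       s = \frac{\sigma_{xy} + C_3}{\sigma_x\sigma_y + C_3}.}
#' With the default exponents (all 1) and \eqn{C_3 = C_2/2} the contrast
#' and structure terms are combined algebraically, which avoids square
#' roots and makes `ssim(I, I)` exactly 1. Identical images score 1; the
#' score is bounded above by 1 for equal exponents. The structure term of
#' the stabilized form can be negative for strongly anti-correlated
#' windows, so the overall score can dip below 0; it is reported raw,
#' never clamped.
#'
#' Defaults (11 x 11 window, Gaussian sigma 1.5,
#' \eqn{C_1 = (0.01\,\mathrm{MAX}_I)^2}, \eqn{C_2 = (0.03\,\mathrm{MAX}_I)^2},
#' \eqn{C_3 = C_2/2}, unit exponents) follow the de-facto standard SSIM
#' configuration; all are adjustable.
#'
#' @param pair an [ImagePair-class]; images must be at least
#'   `windowSize` x `windowSize`.
#' @param windowSize odd window side length, >= 3.
#' @param gaussianSigma width of the Gaussian window weighting.
#' @param alpha,beta,gamma non-negative exponents of the three terms.
#' @param c1,c2,c3 stabilization constants; `NULL` means the defaults
#'   above.
#' @return A single number, 1 for identical images.
#' @examples
#' img <- matrix(runif(64 * 64, 0, 255), 64)
#' ssim(ImagePair(img, img))  # exactly 1
#' @export
ssim <- function(pair, windowSize = 11L, gaussianSigma = 1.5,
                 alpha = 1, beta = 1, gamma = 1,
                 c1 = NULL, c2 = NULL, c3 = NULL) {
  stopifnot(is(pair, "ImagePair"))
  w <- as.integer(windowSize)
  if (w < 3L || w %% 2L == 0L)
    stop("windowSize must be odd and at least 3")
  if (any(c(alpha, beta, gamma) < 0))
    stop("exponents must be non-negative")
  I <- pair@reference; K <- pair@test
  if (nrow(I) < w || ncol(I) < w)
    stop(sprintf("images (%d x %d) are smaller than the %d x %d window",
                 nrow(I), ncol(I), w, w))
  mx <- pair@maxIntensity
  if (is.null(c1)) c1 <- (0.01 * mx)^2
  if (is.null(c2)) c2 <- (0.03 * mx)^2
  if (is.null(c3)) c3 <- c2 / 2
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive")

  off <- seq_len(w) - (w + 1) / 2
  k <- exp(-off^2 / (2 * gaussianSigma^2))
  k <- k / sum(k)

  ux <- .filterValid(I, k)
  uy <- .filterValid(K, k)
  ## weighted second moments (raw; rounding can leave a tiny negative
  ## residue, clamped only where a square root is taken)
  vx <- .filterValid(I * I, k) - ux * ux
  vy <- .filterValid(K * K, k) - uy * uy
  cxy <- .filterValid(I * K, k) - ux * uy

  l <- (2 * ux * uy + c1) / (ux * ux + uy * uy + c1)
  if (beta == gamma && isTRUE(all.equal(c3, c2 / 2)) ) {
    ## combined contrast-structure term: (2 sigma_xy + C2) / (vx + vy + C2)
    cs <- (2 * cxy + c2) / (vx + vy + c2)
    smap <- .signedPow(l, alpha) * .signedPow(cs, beta)
  } else {
    sx <- sqrt(pmax(vx, 0)); sy <- sqrt(pmax(vy, 0))
    cterm <- (2 * sx * sy + c2) / (vx + vy + c2)
    sterm <- (cxy + c3) / (sx * sy + c3)
    smap <- .signedPow(l, alpha) * .signedPow(cterm, beta) *
      .signedPow(sterm, gamma)
  }
  mean(smap)
}

## sign-preserving power, so fractional exponents of the (possibly
## negative) structure term stay real
.signedPow <- function(x, p) {
  if (p == 1) return(x)
  sign(x) * abs(x)^p
}

#' Visual analogue scale discomfort band
#'
#' Bands a 0-10 visual analogue scale (VAS) pain score into the standard
#' discomfort categories: 0-2 comfortable, above 2 up to 4 mild discomfort,
#' up to 6 moderate, up to 8 severe, and up to 10 extreme discomfort.
#'
#' @param score numeric in `[0, 10]` (vectorized).
#' @return Character vector of band labels.
#' @examples
#' vasBand(c(1, 7))
#' @export
vasBand <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 10))
    stop("VAS score must lie in [0, 10]")
  ifelse(score <= 2, "comfortable",
         ifelse(score <= 4, "mild discomfort",
                ifelse(score <= 6, "moderate discomfort",
                       ifelse(score <= 8, "severe discomfort",
                              "extreme discomfort"))))
}

#' Compare reconstruction algorithms against a reference image
#'
#' Evaluates each labeled test image against the reference with PSNR (plus
#' its quality band) and SSIM, returning a [QualityReport-class] with one
#' row per algorithm in input order — the shape of the printed comparison
#' tables used when benchmarking ultrasound reconstruction and denoising
#' algorithms.
#'
#' @param reference numeric matrix, the reference image.
#' @param tests named list of test images (possibly empty); names are the
#'   algorithm labels.
#' @param maxIntensity peak intensity MAX_I, default 255.
#' @param referenceDescription free text recorded in the report.
#' @param ... further arguments passed to [ssim()].
#' @return A [QualityReport-class].
#' @export
compareAlgorithms <- function(reference, tests, maxIntensity = 255,
                              referenceDescription = "reference", ...) {
  reference <- as.matrix(reference)
  if (length(tests) && is.null(names(tests)))
    names(tests) <- paste0("algorithm_", seq_along(tests))
  rows <- lapply(seq_along(tests), function(i) {
    label <- names(tests)[i]
    img <- as.matrix(tests[[i]])
    if (!identical(dim(img), dim(reference)))
      stop(sprintf("dimension mismatch for '%s': %d x %d vs reference %d x %d",
                   label, nrow(img), ncol(img), nrow(reference),
                   ncol(reference)))
    pair <- ImagePair(reference, img, maxIntensity)
    p <- psnr(pair)
    s <- ssim(pair, ...)
    data.frame(algorithm = label, psnr_db = p, psnr_band = psnrBand(p),
               ssim = s, ssim_negative = s < 0,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(algorithm = character(0), psnr_db = numeric(0),
               psnr_band = character(0), ssim = numeric(0),
               ssim_negative = logical(0), stringsAsFactors = FALSE)
  new("QualityReport", table = tab,
      referenceDescription = referenceDescription)
}
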