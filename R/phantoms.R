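#' @include depth-surface.R
NULL

#' Synthetic depth-image phantom with known ground truth
#'
#' Samples a known surface patch on the pixel grid (through the centered
#' image-plane coordinates of [imageToPlaneCoords()]), adds Gaussian noise,
#' and replaces a fixed fraction of pixels with gross outliers of fixed
#' additive magnitude. Returning the generating patch and the outlier set
#' alongside the image makes parameter-recovery and robustness tests
#' self-contained: no external depth data is needed. Outliers are additive
#' at fixed magnitude (not uniform-random) so robust-fit oracle tests stay
#' deterministic. The generator is a pure function of its arguments — the
#' same seed always reproduces the same phantom bit for bit.
#'
#' @param nRows,nCols image dimensions.
#' @param patch the generating [SurfacePatch-class] (a plane or any higher
#'   tier).
#' @param noiseSigma standard deviation of the additive Gaussian depth
#'   noise (same units as depth); 0 for a noiseless phantom.
#' @param outlierFrac fraction of pixels replaced by outliers, in
#'   `[0, 0.5)` (the least-median-of-squares breakdown bound); the outlier
#'   count is `round(outlierFrac * nRows * nCols)`.
#' @param outlierMagnitude depth offset added to outlier pixels.
#' @param seed RNG seed.
#' @return A list with components `image` ([DepthImage-class]), `patch`
#'   (the ground truth), and `outliers` (column-major linear pixel indices
#'   of the corrupted pixels).
#' @examples
#' ph <- makeDepthPhantom(16, 16, SurfacePatch(1, c(5, 0.3, -0.2)),
#'                        noiseSigma = 0.1, outlierFrac = 0.2,
#'                        outlierMagnitude = 50, seed = 7)
#' length(ph$outliers)  # round(0.2 * 256) = 51
#' @export
makeDepthPhantom <- function(nRows, nCols, patch, noiseSigma = 0,
                             outlierFrac = 0, outlierMagnitude = 0,
                             seed = 1L) {
  stopifnot(is(patch, "SurfacePatch"))
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  if (nRows < 1L || nCols < 1L) stop("dimensions must be positive")
  if (noiseSigma < 0) stop("noiseSigma must be non-negative")
  if (outlierFrac < 0 || outlierFrac >= 0.5)
    stop("outlierFrac must lie in [0, 0.5)")
  a <- matrix(rep(0:(nRows - 1L), nCols), nRows)
  b <- matrix(rep(0:(nCols - 1L), each = nRows), nRows)
  pc <- imageToPlaneCoords(as.vector(a), as.vector(b), nRows, nCols)
  depths <- matrix(evalPatch(patch, pc$xb, pc$ya), nRows, nCols)
  N <- nRows * nCols
  nOut <- round(outlierFrac * N)
  out <- .withSeed(seed, {
    noisy <- depths
    if (noiseSigma > 0)
      noisy <- noisy + matrix(stats::rnorm(N, sd = noiseSigma), nRows)
    idx <- if (nOut > 0) sort(sample.int(N, nOut)) else integer(0)
    noisy[idx] <- noisy[idx] + outlierMagnitude
    list(depths = noisy, idx = idx)
  })
  list(image = DepthImage(out$depths), patch = patch, outliers = out$idx)
}

#' Convert a depth phantom to a scattered 3D point set
#'
#' Flattens a depth image into the (x, y, z) point set consumed by the
#' surface regression functions, using the centered image-plane coordinates
#' as (x, y) and dropping masked pixels.
#'
#' @param img a [DepthImage-class].
#' @return An n x 3 matrix with columns x, y, z (column-major pixel order).
#' @export
depthImageToPoints <- function(img) {
  stopifnot(is(img, "DepthImage"))
  n <- nrow(img@depths); m <- ncol(img@depths)
  a <- rep(0:(n - 1L), m)
  b <- rep(0:(m - 1L), each = n)
  pc <- imageToPlaneCoords(a, b, n, m)
  keep <- as.vector(img@validMask)
  cbind(x = pc$xb, y = pc$ya, z = as.vector(img@depths))[keep, , drop = FALSE]
}

#' Analytic voxel-volume phantoms
#'
#' Samples a known scalar field on a regular lattice so that isosurface
#' extraction can be audited against closed-form geometry:
#' `"sphere_volume"` samples the squared distance
#' \eqn{f = x^2 + y^2 + z^2} about the grid center (its iso level
#' \eqn{c = r^2} is an exact sphere of radius r), and `"ramp_volume"`
#' samples \eqn{f = x} (its iso levels are planes). Lattice values match
#' the analytic field exactly at every sample.
#'
#' @param kind `"sphere_volume"` or `"ramp_volume"`.
#' @param dims lattice size (nx, ny, nz), each at least 2.
#' @param spacing lattice step, scalar or length 3.
#' @param origin world position of lattice index (0,0,0); default centers
#'   the sphere field at 0 by construction.
#' @return A list with components `grid` ([VoxelGrid-class]) and `field`, a
#'   function of an n x 3 matrix of world points returning the analytic
#'   field values.
#' @export
makeVolumePhantom <- function(kind = c("sphere_volume", "ramp_volume"),
                              dims = c(17L, 17L, 17L), spacing = 0.25,
                              origin = NULL) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 2L))
    stop("dims must be three integers, each at least 2")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (is.null(origin)) origin <- -(dims - 1L) / 2 * spacing
  xs <- origin[1] + (0:(dims[1] - 1L)) * spacing[1]
  ys <- origin[2] + (0:(dims[2] - 1L)) * spacing[2]
  zs <- origin[3] + (0:(dims[3] - 1L)) * spacing[3]
  center <- origin + (dims - 1L) / 2 * spacing
  if (kind == "sphere_volume") {
    field <- function(p) {
      p <- matrix(as.numeric(p), ncol = 3L)
      (p[, 1L] - center[1])^2 + (p[, 2L] - center[2])^2 +
        (p[, 3L] - center[3])^2
    }
  } else {
    field <- function(p) matrix(as.numeric(p), ncol = 3L)[, 1L]
  }
  vals <- array(0, dims)
  for (k in seq_along(zs))
    vals[, , k] <- outer(xs, ys, function(x, y)
      field(cbind(x, y, zs[k])))
  list(grid = VoxelGrid(vals, origin = origin, spacing = spacing),
       field = field)
}

#' Speckle-degraded image pair
#'
#' Degrades a clean image with multiplicative Gaussian speckle,
#' \eqn{K = \mathrm{clip}(I (1 + \eta),\, 0,\, \mathrm{MAX}_I)} with
#' \eqn{\eta \sim N(0, \sigma^2)} — a standard first-order surrogate for
#' ultrasound speckle — and returns the reference/test pair for the quality
#' metrics. `noiseSigma = 0` returns a bit-identical pair.
#'
#' @param clean numeric matrix, the reference image (in
#'   `[0, maxIntensity]`).
#' @param noiseSigma speckle standard deviation (relative, unitless).
#' @param seed RNG seed; same seed, same pair.
#' @param maxIntensity peak intensity, default 255.
#' @return An [ImagePair-class].
#' @export
makeSpecklePair <- function(clean, noiseSigma, seed = 1L,
                            maxIntensity = 255) {
  clean <- as.matrix(clean)
  if (noiseSigma < 0) stop("noiseSigma must be non-negative")
  K <- if (noiseSigma == 0) clean else .withSeed(seed, {
    eta <- matrix(stats::rnorm(length(clean), sd = noiseSigma), nrow(clean))
    pmin(pmax(clean * (1 + eta), 0), maxIntensity)
  })
  ImagePair(clean, K, maxIntensity)
}

#' Hyperechoic honeycomb phantom image
#'
#' Emulates the bright "honeycomb" cross-sectional appearance of the
#' sciatic nerve on B-mode ultrasound: a hexagonal lattice of bright cell
#' walls (the hyperechoic perineurium) around darker fascicle interiors,
#' with multiplicative speckle on top. Walls are drawn where a pixel is
#' nearly equidistant from its two closest lattice centers (the Voronoi
#' boundary of a hexagonal lattice is the honeycomb). Intensities are
#' clipped to `[0, 255]`.
#'
#' @param nRows,nCols image dimensions.
#' @param cellRadius fascicle cell radius in pixels (> 0).
#' @param wallIntensity intensity of the bright walls; must exceed
#'   `background`.
#' @param background intensity of the cell interiors.
#' @param wallWidth wall half-thickness criterion in pixels.
#' @param speckleSigma multiplicative speckle standard deviation.
#' @param seed RNG seed.
#' @return Numeric matrix in `[0, 255]`.
#' @export
makeHoneycombImage <- function(nRows = 128L, nCols = 128L, cellRadius = 9,
                               wallIntensity = 220, background = 60,
                               wallWidth = NULL, speckleSigma = 0.05,
                               seed = 1L) {
  if (cellRadius <= 0) stop("cellRadius must be positive")
  if (wallIntensity <= background)
    stop("wallIntensity must exceed background")
  if (is.null(wallWidth)) wallWidth <- 0.3 * cellRadius
  sx <- sqrt(3) * cellRadius   # horizontal center spacing
  sy <- 1.5 * cellRadius       # vertical center spacing
  rowsC <- seq(-sy, nRows - 1 + sy, by = sy)
  colsC <- seq(-sx, nCols - 1 + sx, by = sx)
  centers <- do.call(rbind, lapply(seq_along(rowsC), function(i) {
    shift <- if (i %% 2 == 0) sx / 2 else 0
    cbind(rowsC[i], colsC + shift)
  }))
  pr <- rep(0:(nRows - 1L), nCols)
  pc <- rep(0:(nCols - 1L), each = nRows)
  ## distance from every pixel to every center; keep the two smallest
  d2 <- outer(pr, centers[, 1L], "-")^2 + outer(pc, centers[, 2L], "-")^2
  two <- t(apply(d2, 1L, function(r) sqrt(sort.int(r, partial = 1:2)[1:2])))
  wall <- (two[, 2L] - two[, 1L]) < wallWidth
  img <- matrix(ifelse(wall, wallIntensity, background), nRows, nCols)
  if (speckleSigma > 0)
    img <- .withSeed(seed, {
      eta <- matrix(stats::rnorm(length(img), sd = speckleSigma), nRows)
      pmin(pmax(img * (1 + eta), 0), 255)
    })
  img
}
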