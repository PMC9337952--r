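#' @import methods
NULL

## Coefficient counts for the nested polynomial patch family, tiers 1..5:
## plane, bilinear, hyperboloid (full quadratic), bicubic, quartic.
.TIER_NCOEF <- c(3L, 4L, 6L, 10L, 15L)

## Monomial exponents (p, q) for x^p * y^q, in coefficient order a0..a14.
## The first k rows give the design of a tier whose coefficient count is k.
.PATCH_EXPONENTS <- matrix(c(
  0L, 0L,
  1L, 0L,
  0L, 1L,
  1L, 1L,
  2L, 0L,
  0L, 2L,
  3L, 0L,
  2L, 1L,
  1L, 2L,
  0L, 3L,
  4L, 0L,
  3L, 1L,
  2L, 2L,
  1L, 3L,
  0L, 4L), ncol = 2L, byrow = TRUE,
  dimnames = list(NULL, c("p", "q")))

#' SurfacePatch: a member of the nested polynomial surface family
#'
#' A surface patch \eqn{z = f(x, y)} drawn from the cumulative polynomial
#' family used for local surface reconstruction: tier 1 is the plane
#' \eqn{a_0 + a_1 x + a_2 y}, tier 2 adds the bilinear term \eqn{a_3 xy},
#' tier 3 adds \eqn{a_4 x^2 + a_5 y^2}, tier 4 the cubic terms and tier 5
#' the quartic terms, for a maximum of 15 coefficients \eqn{a_0 \ldots a_{14}}.
#' Zero-padding a lower tier into a higher one leaves every evaluated value
#' unchanged, so the tiers are strictly nested.
#'
#' @slot tier integer in 1..5 selecting the family member.
#' @slot coeffs numeric coefficient vector; its length must equal 3, 4, 6,
#'   10 or 15 according to the tier.
#' @seealso [evalPatch()], [leastSquaresFit()], [SurfacePatch()]
#' @export
setClass("SurfacePatch",
  representation(tier = "integer", coeffs = "numeric"))

setValidity("SurfacePatch", function(object) {
  t <- object@tier
  if (length(t) != 1L || is.na(t) || t < 1L || t > 5L)
    return("tier must be a single integer in 1..5")
  want <- .TIER_NCOEF[t]
  if (length(object@coeffs) != want)
    return(sprintf("tier %d requires %d coefficients, got %d",
                   t, want, length(object@coeffs)))
  if (any(!is.finite(object@coeffs)))
    return("coefficients must be finite")
  TRUE
})

#' Construct a SurfacePatch
#'
#' @param tier integer in 1..5 (plane .. quartic).
#' @param coeffs numeric coefficients, length 3, 4, 6, 10 or 15 matching
#'   the tier.
#' @return A [SurfacePatch-class] object.
#' @examples
#' ramp <- SurfacePatch(1, c(0, 1, 2))   # z = x + 2 y
#' evalPatch(ramp, 1, 1)
#' @export
SurfacePatch <- function(tier, coeffs) {
  new("SurfacePatch", tier = as.integer(tier), coeffs = as.numeric(coeffs))
}

#' DepthImage: a rectangular grid of depth samples with a validity mask
#'
#' Stores one depth sample per pixel of an n-row by m-column image together
#' with a per-pixel logical mask; masked-out pixels are never used by any
#' fitting or interpolation operation. Pixel indices are 0-based: the row
#' index `a` runs over the n rows and the column index `b` over the m
#' columns, matching the image-plane coordinate convention of
#' [imageToPlaneCoords()].
#'
#' @slot depths numeric matrix (n x m) of depth samples, arbitrary length
#'   units.
#' @slot validMask logical matrix of identical shape; `FALSE` marks invalid
#'   pixels.
#' @export
setClass("DepthImage",
  representation(depths = "matrix", validMask = "matrix"))

setValidity("DepthImage", function(object) {
  d <- object@depths
  m <- object@validMask
  if (!is.numeric(d) || nrow(d) < 1L || ncol(d) < 1L)
    return("depths must be a numeric matrix with at least one row and column")
  if (!is.logical(m) || !identical(dim(m), dim(d)))
    return("validMask must be a logical matrix with the same shape as depths")
  if (any(!is.finite(d[m])))
    return("valid pixels must hold finite depths")
  TRUE
})

#' Construct a DepthImage
#'
#' @param depths numeric matrix of depth samples.
#' @param validMask logical matrix of the same shape; defaults to all-valid.
#' @return A [DepthImage-class] object.
#' @export
DepthImage <- function(depths, validMask = NULL) {
  depths <- as.matrix(depths)
  storage.mode(depths) <- "double"
  if (is.null(validMask))
    validMask <- matrix(TRUE, nrow(depths), ncol(depths))
  new("DepthImage", depths = depths, validMask = validMask)
}

#' FitResult: a fitted surface patch with its goodness-of-fit summaries
#'
#' Bundles the fitted [SurfacePatch-class] with the chi-square objective
#' (the sum of squared residuals over all points), the least-median-of-
#' squares objective (the lower median of the squared residuals), and a
#' per-point inlier mask. Both stored statistics are recomputable from the
#' patch and the data.
#'
#' @slot patch the fitted [SurfacePatch-class].
#' @slot chiSquare sum of squared residuals of `patch` over all fitted
#'   points.
#' @slot medianSqResidual lower median of the squared residuals of `patch`.
#' @slot inlierMask logical vector, one flag per fitted point.
#' @export
setClass("FitResult",
  representation(patch = "SurfacePatch", chiSquare = "numeric",
                 medianSqResidual = "numeric", inlierMask = "logical"))

setValidity("FitResult", function(object) {
  if (length(object@chiSquare) != 1L || !is.finite(object@chiSquare) ||
      object@chiSquare < 0)
    return("chiSquare must be a single non-negative finite number")
  if (length(object@medianSqResidual) != 1L ||
      !is.finite(object@medianSqResidual) || object@medianSqResidual < 0)
    return("medianSqResidual must be a single non-negative finite number")
  TRUE
})

#' VoxelGrid: a regular 3D lattice of scalar samples
#'
#' A scalar field \eqn{f(x, y, z)} sampled on a regular lattice. The world
#' position of lattice index \eqn{(i, j, k)} (0-based) is
#' `origin + c(i, j, k) * spacing`. Cell-based operations (trilinear
#' interpolation, isosurface extraction) require at least two samples per
#' axis.
#'
#' @slot values numeric 3D array (nx x ny x nz).
#' @slot origin numeric length-3 world position of lattice index (0,0,0).
#' @slot spacing positive numeric length-3 lattice step along x, y, z.
#' @export
setClass("VoxelGrid",
  representation(values = "array", origin = "numeric", spacing = "numeric"))

setValidity("VoxelGrid", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L)
    return("values must be a 3D array")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be a finite length-3 numeric")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be strictly positive along every axis")
  TRUE
})

#' Construct a VoxelGrid
#'
#' @param values numeric 3D array of scalar samples.
#' @param origin world coordinates of lattice index (0,0,0); default c(0,0,0).
#' @param spacing lattice step along (x, y, z); scalar or length 3.
#' @return A [VoxelGrid-class] object.
#' @export
VoxelGrid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VoxelGrid", values = values, origin = as.numeric(origin),
      spacing = as.numeric(spacing))
}

#' TrilinearCell: the degree-(1,1,1) interpolant of one voxel cell
#'
#' The unique trilinear polynomial
#' \deqn{f(x,y,z) = a_0 + a_1 x + a_2 y + a_3 z + a_4 xy + a_5 yz
#'       + a_6 zx + a_7 xyz}
#' interpolating the 8 corner values of a unit cube. Corners are ordered by
#' the (z, y, x) bit pattern: corner index \eqn{i} (0-based) sits at
#' \eqn{x = i \bmod 2}, \eqn{y = (i \div 2) \bmod 2}, \eqn{z = i \div 4}.
#'
#' @slot cornerValues numeric length 8, corner samples in bit-pattern order.
#' @slot coeffs numeric length 8, the coefficients \eqn{a_0 \ldots a_7}.
#' @export
setClass("TrilinearCell",
  representation(cornerValues = "numeric", coeffs = "numeric"))

setValidity("TrilinearCell", function(object) {
  if (length(object@cornerValues) != 8L || any(!is.finite(object@cornerValues)))
    return("cornerValues must be 8 finite numbers")
  if (length(object@coeffs) != 8L)
    return("coeffs must have length 8")
  TRUE
})

#' TriMesh: an indexed triangle mesh
#'
#' Vertices in world coordinates plus triangles as 1-based vertex index
#' triples, as produced by [extractIsosurface()]. `isoValue` records the
#' level-set constant the mesh approximates.
#'
#' @slot vertices numeric matrix (nVertices x 3).
#' @slot triangles integer matrix (nTriangles x 3), 1-based indices.
#' @slot isoValue the iso level the mesh was extracted at.
#' @export
setClass("TriMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 isoValue = "numeric"))

setValidity("TriMesh", function(object) {
  v <- object@vertices
  f <- object@triangles
  if (ncol(v) != 3L && nrow(v) > 0L) return("vertices must have 3 columns")
  if (ncol(f) != 3L && nrow(f) > 0L) return("triangles must have 3 columns")
  if (nrow(f) > 0L) {
    if (any(f < 1L) || any(f > nrow(v)))
      return("triangle indices out of range")
    if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
      return("a triangle repeats a vertex index")
  }
  TRUE
})

#' ImagePair: a reference/test image pair for full-reference quality metrics
#'
#' Two monochrome images of identical dimensions with a fixed peak
#' intensity `maxIntensity` (MAX_I). Intensities must lie in
#' `[0, maxIntensity]`. The peak is part of the pair's contract and is never
#' inferred from the data (default 255 for 8-bit images).
#'
#' @slot reference numeric matrix, the undistorted image I.
#' @slot test numeric matrix, the image K under evaluation.
#' @slot maxIntensity positive peak intensity MAX_I.
#' @export
setClass("ImagePair",
  representation(reference = "matrix", test = "matrix",
                 maxIntensity = "numeric"))

setValidity("ImagePair", function(object) {
  I <- object@reference; K <- object@test
  if (!identical(dim(I), dim(K)))
    return(sprintf("dimension mismatch: reference %dx%d vs test %dx%d",
                   nrow(I), ncol(I), nrow(K), ncol(K)))
  mx <- object@maxIntensity
  if (length(mx) != 1L || !is.finite(mx) || mx <= 0)
    return("maxIntensity must be a single positive number")
  if (any(!is.finite(I)) || any(!is.finite(K)))
    return("intensities must be finite")
  if (min(I, K) < 0 || max(I, K) > mx)
    return("intensities must lie in [0, maxIntensity]")
  TRUE
})

#' Construct an ImagePair
#'
#' @param reference numeric matrix, the reference image.
#' @param test numeric matrix of identical dimensions.
#' @param maxIntensity peak intensity MAX_I; default 255 (8-bit).
#' @return An [ImagePair-class] object.
#' @export
ImagePair <- function(reference, test, maxIntensity = 255) {
  new("ImagePair", reference = as.matrix(reference) + 0,
      test = as.matrix(test) + 0, maxIntensity = as.numeric(maxIntensity))
}

#' QualityReport: a per-algorithm table of image-quality metrics
#'
#' One row per evaluated algorithm with its PSNR (dB), PSNR quality band,
#' and SSIM, in input order; the shape of the printed comparison tables in
#' the ultrasound image-quality literature. SSIM values below zero (the
#' structure term of the stabilized form can be negative) are reported raw
#' and flagged in the `ssim_negative` column rather than clamped.
#'
#' @slot table data.frame with columns `algorithm`, `psnr_db`, `psnr_band`,
#'   `ssim`, `ssim_negative`.
#' @slot referenceDescription free-text description of the reference image.
#' @export
setClass("QualityReport",
  representation(table = "data.frame", referenceDescription = "character"))

setValidity("QualityReport", function(object) {
  need <- c("algorithm", "psnr_db", "psnr_band", "ssim", "ssim_negative")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  TRUE
})
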