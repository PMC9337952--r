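#' @include AllClasses.R
NULL

## Evaluate the local RNG: run expr under a fixed seed without disturbing
## the caller's random stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Map pixel indices to centered image-plane coordinates
#'
#' For an image with `nRows` (n) rows and `nCols` (m) columns, pixel
#' \eqn{(a, b)} — `a` the 0-based row index, `b` the 0-based column index —
#' maps to the centered image-plane coordinates
#' \deqn{x_b = b - (m - 1)/2, \qquad y_a = -a + (n - 1)/2,}
#' so the image center is the origin, x grows to the right and y grows
#' upward. Real-valued (sub-pixel) indices are accepted; the mapping is
#' affine and exactly invertible via [planeToImageCoords()].
#'
#' @param a 0-based row index (vectorized, real-valued allowed), in
#'   `[0, nRows - 1]`.
#' @param b 0-based column index, in `[0, nCols - 1]`.
#' @param nRows,nCols image dimensions n and m.
#' @return A list with numeric components `xb` and `ya`.
#' @examples
#' imageToPlaneCoords(0, 0, 5, 5)   # top-left pixel -> (-2, 2)
#' @export
imageToPlaneCoords <- function(a, b, nRows, nCols) {
  if (any(a < 0 | a > nRows - 1))
    stop("row index 'a' out of range [0, nRows - 1]")
  if (any(b < 0 | b > nCols - 1))
    stop("column index 'b' out of range [0, nCols - 1]")
  list(xb = b - (nCols - 1) / 2, ya = -a + (nRows - 1) / 2)
}

#' @rdname imageToPlaneCoords
#' @param xb,ya image-plane coordinates to map back to pixel indices.
#' @export
planeToImageCoords <- function(xb, ya, nRows, nCols) {
  list(a = (nRows - 1) / 2 - ya, b = xb + (nCols - 1) / 2)
}

## Design matrix of patch monomials at (x, y) for a given coefficient count.
.patchDesign <- function(x, y, ncoef) {
  ex <- .PATCH_EXPONENTS[seq_len(ncoef), , drop = FALSE]
  D <- vapply(seq_len(ncoef),
              function(j) x^ex[j, 1L] * y^ex[j, 2L],
              numeric(length(x)))
  if (length(x) == 1L) D <- matrix(D, nrow = 1L)
  D
}

#' Evaluate a surface patch
#'
#' Evaluates the cumulative polynomial \eqn{z_t(x, y)} of the patch's tier
#' at the given coordinates. Vectorized over `x` and `y`.
#'
#' @param patch a [SurfacePatch-class].
#' @param x,y evaluation coordinates (numeric vectors of equal length, or
#'   one of them scalar).
#' @return Numeric vector of depths.
#' @examples
#' evalPatch(SurfacePatch(1, c(1, 2, 3)), 1, 1)  # 6
#' @export
evalPatch <- function(patch, x, y) {
  stopifnot(is(patch, "SurfacePatch"))
  validObject(patch)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  drop(.patchDesign(x, y, length(patch@coeffs)) %*% patch@coeffs)
}

#' Fit the plane through three non-collinear 3D points
#'
#' Solves for the tier-1 patch \eqn{z_{ab} = a_0 + a_1 x_b + a_2 y_a}
#' passing exactly through three points whose (x, y) projections are not
#' collinear; the local model used to read a depth off the plane spanned by
#' three stored depth-image points.
#'
#' @param p1,p2,p3 numeric length-3 vectors (x, y, z).
#' @return A tier-1 [SurfacePatch-class] reproducing the three depths
#'   exactly.
#' @examples
#' fitPlaneFromPoints(c(0, 0, 5), c(1, 0, 5), c(0, 1, 5))  # z = 5
#' @export
fitPlaneFromPoints <- function(p1, p2, p3) {
  P <- rbind(p1, p2, p3)
  if (!is.numeric(P) || ncol(P) != 3L || any(!is.finite(P)))
    stop("each point must be a finite numeric (x, y, z) triple")
  A <- cbind(1, P[, 1L], P[, 2L])
  scale <- max(1, max(abs(P[, 1:2])))^2
  if (abs(det(A)) <= 1e-12 * scale)
    stop("degenerate geometry: the three points project to collinear (x, y) locations")
  SurfacePatch(1L, solve(A, P[, 3L]))
}

#' Interpolate a depth image at a sub-pixel location
#'
#' Triangular surface interpolation: the unit pixel quad enclosing the
#' query is split into two triangles along the fixed
#' \eqn{(a_0, b_0)}–\eqn{(a_1, b_1)} diagonal and the planar (barycentric)
#' interpolant of the three enclosing corner depths is returned. At integer
#' indices the stored depth is reproduced exactly, and any globally planar
#' depth field is reproduced exactly everywhere.
#'
#' @param img a [DepthImage-class].
#' @param a,b real-valued 0-based row/column query positions (vectorized).
#' @return Numeric vector of interpolated depths.
#' @export
interpolateDepth <- function(img, a, b) {
  stopifnot(is(img, "DepthImage"))
  n <- nrow(img@depths); m <- ncol(img@depths)
  k <- max(length(a), length(b))
  a <- rep_len(as.numeric(a), k)
  b <- rep_len(as.numeric(b), k)
  if (any(a < 0 | a > n - 1))
    stop("row index 'a' out of range [0, nRows - 1]")
  if (any(b < 0 | b > m - 1))
    stop("column index 'b' out of range [0, nCols - 1]")
  a0 <- pmin(floor(a), n - 2); b0 <- pmin(floor(b), m - 2)
  if (n == 1L) a0 <- rep_len(0, k)
  if (m == 1L) b0 <- rep_len(0, k)
  u <- a - a0; v <- b - b0
  out <- numeric(k)
  for (i in seq_len(k)) {
    r0 <- a0[i] + 1L; c0 <- b0[i] + 1L
    r1 <- min(r0 + 1L, n); c1 <- min(c0 + 1L, m)
    if (!all(img@validMask[c(r0, r1), c(c0, c1)]))
      stop("masked data: an enclosing corner of the query pixel quad is invalid")
    z00 <- img@depths[r0, c0]; z01 <- img@depths[r0, c1]
    z10 <- img@depths[r1, c0]; z11 <- img@depths[r1, c1]
    out[i] <- if (u[i] >= v[i])
      z00 + u[i] * (z10 - z00) + v[i] * (z11 - z10)
    else
      z00 + v[i] * (z01 - z00) + u[i] * (z11 - z01)
  }
  out
}
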