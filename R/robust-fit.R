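#' @include depth-surface.R
NULL

## Coerce a point set to an n x 3 matrix with columns x, y, z. Accepts a
## matrix or a data.frame with named columns.
.asPoints <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x", "y", "z") %in% names(points)))
      points <- as.matrix(points[, c("x", "y", "z")])
    else
      points <- as.matrix(points)
  }
  if (!is.matrix(points) || ncol(points) != 3L)
    stop("points must be an n x 3 matrix or data.frame with columns x, y, z")
  storage.mode(points) <- "double"
  if (nrow(points) < 1L) stop("point set must contain at least one point")
  if (any(!is.finite(points))) stop("point coordinates must be finite")
  points
}

## Lower median: for even n, the smaller of the two middle order statistics.
.lowerMedian <- function(x) sort(x)[ceiling(length(x) / 2)]

.sqResiduals <- function(patch, points) {
  (points[, 3L] - evalPatch(patch, points[, 1L], points[, 2L]))^2
}

#' Chi-square objective of a patch over a point set
#'
#' The sum of squared residuals
#' \eqn{\chi^2 = \sum_a (z_a - f(x_a, y_a))^2} of a surface patch over a
#' scattered 3D point set; the regression objective minimized by
#' [leastSquaresFit()].
#'
#' @param patch a [SurfacePatch-class].
#' @param points n x 3 matrix or data.frame (columns x, y, z).
#' @return A single non-negative number.
#' @export
chiSquare <- function(patch, points) {
  points <- .asPoints(points)
  sum(.sqResiduals(patch, points))
}

.newFitResult <- function(patch, points, inliers = NULL) {
  r2 <- .sqResiduals(patch, points)
  if (is.null(inliers)) inliers <- rep(TRUE, nrow(points))
  new("FitResult", patch = patch, chiSquare = sum(r2),
      medianSqResidual = .lowerMedian(r2), inlierMask = inliers)
}

#' Ordinary least-squares surface fit
#'
#' Fits the tier's polynomial patch to scattered (x, y, z) data by
#' minimizing the chi-square objective (sum of squared residuals). The
#' global minimizer is computed by QR decomposition of the monomial design
#' matrix.
#'
#' @param points n x 3 matrix or data.frame (columns x, y, z).
#' @param tier patch tier in 1..5 (3, 4, 6, 10 or 15 coefficients).
#' @return A [FitResult-class]; `fitChiSquare()` of the result is the
#'   global minimum for that tier.
#' @examples
#' pts <- cbind(x = runif(20), y = runif(20), z = 0)
#' pts[, "z"] <- 1 + 2 * pts[, "x"] - pts[, "y"]
#' leastSquaresFit(pts, tier = 1)
#' @export
leastSquaresFit <- function(points, tier) {
  points <- .asPoints(points)
  tier <- as.integer(tier)
  if (tier < 1L || tier > 5L) stop("tier must be in 1..5")
  p <- .TIER_NCOEF[tier]
  n <- nrow(points)
  if (n < p)
    stop(sprintf("insufficient data: tier %d needs at least %d points, got %d",
                 tier, p, n))
  D <- .patchDesign(points[, 1L], points[, 2L], p)
  qrD <- qr(D)
  if (qrD$rank < p)
    stop("degenerate design: the point locations do not determine the patch")
  coef <- qr.coef(qrD, points[, 3L])
  .newFitResult(SurfacePatch(tier, coef), points)
}

#' Least-median-of-squares robust surface fit
#'
#' Robust regression by the minimum-median-of-squares rule with a
#' resampling strategy: `nSubsets` seeded random minimal subsets (subset
#' size = the tier's coefficient count) are each fitted exactly, every
#' candidate is scored by the lower median over all points of the squared
#' residual \eqn{(z_a - f(x_a, y_a))^2}, and the candidate minimizing that
#' median wins. LMedS tolerates up to half the points being gross outliers,
#' which ordinary least squares does not.
#'
#' With `refine = TRUE` the winning patch is polished by an ordinary
#' least-squares fit on its inliers, where a point is an inlier when its
#' squared residual is at most \eqn{(2.5 s)^2} with the classical robust
#' scale \eqn{s = 1.4826\,(1 + 5/(n - m))\sqrt{\mathrm{med}\, r^2}}.
#'
#' @param points n x 3 matrix or data.frame (columns x, y, z).
#' @param tier patch tier in 1..5.
#' @param nSubsets number of random minimal subsets to draw (>= 1).
#' @param seed RNG seed; identical seeds give bit-identical results.
#' @param refine logical: re-fit by least squares on the inliers of the
#'   winning candidate.
#' @return A [FitResult-class]; `medianSqResidual()` is the LMedS objective
#'   of the returned patch and `inlierMask()` flags the inliers.
#' @export
lmedsFit <- function(points, tier, nSubsets = 500L, seed = 1L,
                     refine = TRUE) {
  points <- .asPoints(points)
  tier <- as.integer(tier)
  if (tier < 1L || tier > 5L) stop("tier must be in 1..5")
  nSubsets <- as.integer(nSubsets)
  if (nSubsets < 1L) stop("nSubsets must be at least 1")
  p <- .TIER_NCOEF[tier]
  n <- nrow(points)
  if (n < p)
    stop(sprintf("insufficient data: tier %d needs at least %d points, got %d",
                 tier, p, n))
  D <- .patchDesign(points[, 1L], points[, 2L], p)
  z <- points[, 3L]

  best <- NULL
  bestMed <- Inf
  .withSeed(seed, {
    for (s in seq_len(nSubsets)) {
      idx <- sample.int(n, p)           # without replacement
      A <- D[idx, , drop = FALSE]
      coef <- tryCatch(solve(A, z[idx]), error = function(e) NULL)
      if (is.null(coef) || any(!is.finite(coef))) next
      med <- .lowerMedian((z - drop(D %*% coef))^2)
      if (med < bestMed) {
        bestMed <- med
        best <- coef
      }
    }
  })
  if (is.null(best))
    stop("degenerate design: no sampled minimal subset was solvable")
  patch <- SurfacePatch(tier, best)

  r2 <- .sqResiduals(patch, points)
  scale <- if (n > p)
    1.4826 * (1 + 5 / (n - p)) * sqrt(bestMed)
  else
    sqrt(bestMed)
  inliers <- r2 <= (2.5 * scale)^2
  if (refine && sum(inliers) >= p) {
    sub <- points[inliers, , drop = FALSE]
    qrD <- qr(.patchDesign(sub[, 1L], sub[, 2L], p))
    if (qrD$rank == p)
      patch <- SurfacePatch(tier, qr.coef(qrD, sub[, 3L]))
  }
  .newFitResult(patch, points, inliers)
}

## Integral of x^p over [lo, hi].
.intPow <- function(p, lo, hi) (hi^(p + 1) - lo^(p + 1)) / (p + 1)

## Thin-plate penalty matrix: P[j, k] = integral over the rectangle of
## d2(phi_j)/dx2 * d2(phi_k)/dx2 + 2 * dxy * dxy + dy2 * dy2, where phi are
## the patch monomials. Exact for polynomials.
.thinPlatePenalty <- function(ncoef, xlim, ylim) {
  ex <- .PATCH_EXPONENTS[seq_len(ncoef), , drop = FALSE]
  ## second-derivative monomials of x^p y^q as (coef, p, q)
  dxx <- function(p, q) c(p * (p - 1), max(p - 2, 0), q)
  dxy <- function(p, q) c(p * q, max(p - 1, 0), max(q - 1, 0))
  dyy <- function(p, q) c(q * (q - 1), p, max(q - 2, 0))
  term <- function(d1, d2) {
    cf <- d1[1] * d2[1]
    if (cf == 0) return(0)
    cf * .intPow(d1[2] + d2[2], xlim[1], xlim[2]) *
      .intPow(d1[3] + d2[3], ylim[1], ylim[2])
  }
  P <- matrix(0, ncoef, ncoef)
  for (j in seq_len(ncoef)) {
    for (k in j:ncoef) {
      pj <- ex[j, 1L]; qj <- ex[j, 2L]
      pk <- ex[k, 1L]; qk <- ex[k, 2L]
      v <- term(dxx(pj, qj), dxx(pk, qk)) +
        2 * term(dxy(pj, qj), dxy(pk, qk)) +
        term(dyy(pj, qj), dyy(pk, qk))
      P[j, k] <- v
      P[k, j] <- v
    }
  }
  P
}

#' Thin-plate regularized surface fit
#'
#' Minimizes the penalized objective
#' \deqn{\chi^2 + \alpha^2 \iint f_{xx}^2 + 2 f_{xy}^2 + f_{yy}^2 \; dx\,dy}
#' over the data's bounding rectangle (or a user-supplied one). The
#' smoothness integral is evaluated in closed form for polynomial patches,
#' so the solution is the exact minimizer of the penalized normal
#' equations. At `alpha = 0` the fit coincides with [leastSquaresFit()];
#' as `alpha` grows the solution is pulled toward the penalty's null space,
#' the affine (plane) surfaces.
#'
#' @param points n x 3 matrix or data.frame (columns x, y, z).
#' @param tier patch tier in 1..5.
#' @param alpha non-negative regularization weight (enters squared).
#' @param xlim,ylim integration rectangle; defaults to the data's bounding
#'   box.
#' @return A [FitResult-class] whose `fitChiSquare()` is the (unpenalized)
#'   sum of squared residuals at the regularized solution.
#' @export
regularizedFit <- function(points, tier, alpha, xlim = NULL, ylim = NULL) {
  points <- .asPoints(points)
  tier <- as.integer(tier)
  if (tier < 1L || tier > 5L) stop("tier must be in 1..5")
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("alpha must be a single non-negative number")
  p <- .TIER_NCOEF[tier]
  n <- nrow(points)
  if (n < 3L)
    stop("insufficient data: regularized fitting needs at least 3 points")
  if (is.null(xlim)) xlim <- range(points[, 1L])
  if (is.null(ylim)) ylim <- range(points[, 2L])
  D <- .patchDesign(points[, 1L], points[, 2L], p)
  if (alpha == 0) {
    if (n < p)
      stop(sprintf("insufficient data: tier %d needs at least %d points at alpha = 0",
                   tier, p))
    return(leastSquaresFit(points, tier))
  }
  P <- .thinPlatePenalty(p, xlim, ylim)
  ## Solve min ||D a - z||^2 + alpha^2 a' P a as an augmented least-squares
  ## problem: stack D with alpha * B where B' B = P (symmetric square
  ## root). Much better conditioned than the penalized normal equations
  ## when alpha is large.
  eP <- eigen(P, symmetric = TRUE)
  B <- sqrt(pmax(eP$values, 0)) * t(eP$vectors)
  Aug <- rbind(D, alpha * B)
  qrA <- qr(Aug, LAPACK = TRUE)
  coef <- qr.coef(qrA, c(points[, 3L], numeric(p)))
  if (any(!is.finite(coef)))
    stop("degenerate design: penalized system is rank deficient")
  .newFitResult(SurfacePatch(tier, drop(coef)), points)
}
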