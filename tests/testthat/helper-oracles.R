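## Independent oracles used across the suite. Each is written as the most
## literal possible transcription of the definition it checks, kept free of
## the package's own code paths.

## Term-by-term monomial sum for the nested patch family, with the
## monomial list of every tier spelled out explicitly.
oracle_patch_terms <- list(
  `1` = list(c(0, 0), c(1, 0), c(0, 1)),
  `2` = list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
  `3` = list(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 0), c(0, 2)),
  `4` = list(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 0), c(0, 2),
             c(3, 0), c(2, 1), c(1, 2), c(0, 3)),
  `5` = list(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 0), c(0, 2),
             c(3, 0), c(2, 1), c(1, 2), c(0, 3),
             c(4, 0), c(3, 1), c(2, 2), c(1, 3), c(0, 4)))

oracle_eval_patch <- function(tier, coeffs, x, y) {
  terms <- oracle_patch_terms[[as.character(tier)]]
  acc <- 0
  for (j in seq_along(terms))
    acc <- acc + coeffs[j] * x^terms[[j]][1] * y^terms[[j]][2]
  acc
}

## Barycentric-coordinate planar interpolation over one triangle: solve the
## 3x3 system for the barycentric weights of the query point directly.
oracle_barycentric <- function(tri_xy, tri_z, q) {
  A <- rbind(t(tri_xy), c(1, 1, 1))
  w <- solve(A, c(q, 1))
  sum(w * tri_z)
}

## Double-loop MSE exactly as defined.
oracle_mse <- function(I, K) {
  m <- nrow(I); n <- ncol(I)
  acc <- 0
  for (i in seq_len(m))
    for (j in seq_len(n))
      acc <- acc + (I[i, j] - K[i, j])^2
  acc / (m * n)
}

## Trilinear coefficients by dense solution of the 8x8 interpolation
## system (corner i at x = i %% 2, y = (i %/% 2) %% 2, z = i %/% 4).
oracle_trilinear_coeffs <- function(corners) {
  M <- matrix(0, 8, 8)
  for (i in 0:7) {
    x <- i %% 2; y <- (i %/% 2) %% 2; z <- i %/% 4
    M[i + 1, ] <- c(1, x, y, z, x * y, y * z, z * x, x * y * z)
  }
  solve(M, corners)
}

## Nested 1D linear interpolation: lerp in x, then y, then z.
oracle_nested_lerp <- function(corners, x, y, z) {
  cv <- function(xi, yi, zi) corners[1 + xi + 2 * yi + 4 * zi]
  lerp <- function(a, b, t) a + t * (b - a)
  c00 <- lerp(cv(0, 0, 0), cv(1, 0, 0), x)
  c10 <- lerp(cv(0, 1, 0), cv(1, 1, 0), x)
  c01 <- lerp(cv(0, 0, 1), cv(1, 0, 1), x)
  c11 <- lerp(cv(0, 1, 1), cv(1, 1, 1), x)
  c0 <- lerp(c00, c10, y)
  c1 <- lerp(c01, c11, y)
  lerp(c0, c1, z)
}

## Lower median (for even n, the smaller middle order statistic).
oracle_lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]

## Exhaustive LMedS for tier-1 (plane) fits: enumerate every 3-point
## subset, fit it exactly, and keep the best median of squared residuals.
oracle_lmeds_plane <- function(pts) {
  n <- nrow(pts)
  best <- Inf
  bestCoef <- NULL
  for (s in utils::combn(n, 3, simplify = FALSE)) {
    A <- cbind(1, pts[s, 1], pts[s, 2])
    coef <- tryCatch(solve(A, pts[s, 3]), error = function(e) NULL)
    if (is.null(coef)) next
    r2 <- (pts[, 3] - (coef[1] + coef[2] * pts[, 1] + coef[3] * pts[, 2]))^2
    med <- oracle_lower_median(r2)
    if (med < best) { best <- med; bestCoef <- coef }
  }
  list(median = best, coeffs = bestCoef)
}

## Unordered-edge incidence table of a triangle mesh.
edge_incidence <- function(mesh) {
  tri <- meshTriangles(mesh)
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)])
  table(paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])))
}

## Random patch with coefficients of moderate size, for property loops.
random_patch <- function(tier) {
  ncoef <- c(3, 4, 6, 10, 15)[tier]
  SurfacePatch(tier, stats::runif(ncoef, -2, 2))
}

## Path of the installed command-line script and an Rscript runner.
cli_script <- function() {
  system.file("cli", "sonorecon3d.R", package = "SonoRecon3D")
}

run_cli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  ## forward the running session's library paths to the child process
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out <- suppressWarnings(system2(rscript, c("--vanilla", cli_script(), args),
                                  stdout = TRUE, stderr = TRUE, env = libs))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
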