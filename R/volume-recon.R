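#' @include AllClasses.R
NULL

## Unit-cube corner coordinates in (z, y, x) bit-pattern order: corner i
## sits at x = i %% 2, y = (i %/% 2) %% 2, z = i %/% 4.
.CORNER_XYZ <- cbind(
  x = bitwAnd(0:7, 1L),
  y = bitwAnd(bitwShiftR(0:7, 1L), 1L),
  z = bitwShiftR(0:7, 2L))

#' Trilinear coefficients of a voxel cell
#'
#' Computes the unique coefficients \eqn{a_0 \ldots a_7} of the trilinear
#' polynomial
#' \deqn{f(x,y,z) = a_0 + a_1 x + a_2 y + a_3 z + a_4 xy + a_5 yz
#'       + a_6 zx + a_7 xyz}
#' interpolating the 8 corner samples of a unit cube (corner order: the
#' (z, y, x) bit pattern, see [TrilinearCell-class]). The coefficients are
#' the finite differences of the corner values, the closed-form solution of
#' the 8 x 8 interpolation system.
#'
#' @param cornerValues numeric length 8.
#' @return A [TrilinearCell-class].
#' @examples
#' cellCoefficients(cellCoeffs(rep(7, 8)))  # constant field: a0 = 7
#' @export
cellCoeffs <- function(cornerValues) {
  v <- as.numeric(cornerValues)
  if (length(v) != 8L || any(!is.finite(v)))
    stop("cornerValues must be exactly 8 finite numbers")
  ## corners named by (x, y, z) bits: v[1 + x + 2 y + 4 z]
  c000 <- v[1]; c100 <- v[2]; c010 <- v[3]; c110 <- v[4]
  c001 <- v[5]; c101 <- v[6]; c011 <- v[7]; c111 <- v[8]
  a <- c(
    c000,
    c100 - c000,
    c010 - c000,
    c001 - c000,
    c110 - c100 - c010 + c000,
    c011 - c010 - c001 + c000,
    c101 - c100 - c001 + c000,
    c111 - c110 - c101 - c011 + c100 + c010 + c001 - c000)
  new("TrilinearCell", cornerValues = v, coeffs = a)
}

#' Evaluate a trilinear cell inside the unit cube
#'
#' @param cell a [TrilinearCell-class].
#' @param x,y,z coordinates in `[0, 1]` (vectorized); coordinates outside
#'   the unit cube are an error, never silently clamped.
#' @return Numeric vector of interpolated values; exact at the 8 corners.
#' @export
trilinearEval <- function(cell, x, y, z) {
  stopifnot(is(cell, "TrilinearCell"))
  n <- max(length(x), length(y), length(z))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  z <- rep_len(as.numeric(z), n)
  if (any(x < 0 | x > 1 | y < 0 | y > 1 | z < 0 | z > 1))
    stop("coordinates must lie in the unit cube [0, 1]^3")
  a <- cell@coeffs
  a[1] + a[2] * x + a[3] * y + a[4] * z + a[5] * x * y +
    a[6] * y * z + a[7] * z * x + a[8] * x * y * z
}

#' Evaluate the reduced bilinear 3D patch
#'
#' The six-coefficient surface-patch model
#' \deqn{f(x,y,z) = a_0 + a_1 x + a_2 y + a_3 z + a_4 xy + a_5 yz,}
#' the binary-linear local model of a surface patch in 3-space. Unlike the
#' full trilinear form it carries no `zx` or `xyz` term; both forms are
#' provided as distinct operations.
#'
#' @param coeffs numeric length 6, \eqn{a_0 \ldots a_5}.
#' @param x,y,z evaluation coordinates (vectorized).
#' @return Numeric vector.
#' @export
evalLinearPatch3D <- function(coeffs, x, y, z) {
  a <- as.numeric(coeffs)
  if (length(a) != 6L)
    stop("the reduced 3D patch takes exactly 6 coefficients")
  n <- max(length(x), length(y), length(z))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  z <- rep_len(as.numeric(z), n)
  a[1] + a[2] * x + a[3] * y + a[4] * z + a[5] * x * y + a[6] * y * z
}

#' Trilinear interpolation of a voxel grid at world coordinates
#'
#' Looks up the cell containing each query point and evaluates its
#' trilinear interpolant; queries outside the grid's world bounds are an
#' error.
#'
#' @param grid a [VoxelGrid-class].
#' @param points n x 3 matrix of world (x, y, z) coordinates.
#' @return Numeric vector of field values.
#' @export
interpolateVolume <- function(grid, points) {
  stopifnot(is(grid, "VoxelGrid"))
  points <- matrix(as.numeric(points), ncol = 3L)
  d <- dim(grid@values)
  if (any(d < 2L)) stop("grid needs at least 2 samples per axis")
  ## continuous lattice coordinates
  lc <- sweep(sweep(points, 2L, grid@origin), 2L, grid@spacing, "/")
  if (any(lc < -1e-9) || any(sweep(lc, 2L, d - 1L) > 1e-9))
    stop("query point outside the voxel grid")
  lc <- pmin(pmax(lc, 0), matrix(d - 1L, nrow(lc), 3L, byrow = TRUE))
  i0 <- pmin(floor(lc), matrix(d - 2L, nrow(lc), 3L, byrow = TRUE))
  loc <- lc - i0
  out <- numeric(nrow(points))
  for (q in seq_len(nrow(points))) {
    ix <- i0[q, 1L] + 1L; iy <- i0[q, 2L] + 1L; iz <- i0[q, 3L] + 1L
    corners <- grid@values[cbind(ix + .CORNER_XYZ[, 1L],
                                 iy + .CORNER_XYZ[, 2L],
                                 iz + .CORNER_XYZ[, 3L])]
    out[q] <- trilinearEval(cellCoeffs(corners), loc[q, 1L], loc[q, 2L],
                            loc[q, 3L])
  }
  out
}

## The six tetrahedra of the Kuhn subdivision of the unit cube around the
## main diagonal corner0 -> corner7; every tet is {0, a, b, 7} for an edge
## path 0 -> a -> b -> 7. Using the same split in every cell makes shared
## faces between neighbouring cells triangulate identically, so extracted
## meshes are watertight.
.CUBE_TETS <- matrix(c(
  0L, 1L, 3L, 7L,
  0L, 1L, 5L, 7L,
  0L, 2L, 3L, 7L,
  0L, 2L, 6L, 7L,
  0L, 4L, 5L, 7L,
  0L, 4L, 6L, 7L) + 1L, ncol = 4L, byrow = TRUE)

#' Extract an isosurface mesh from a voxel grid
#'
#' Extracts a triangle mesh approximating the level set
#' \eqn{\{(x,y,z) : f(x,y,z) = c\}} of the sampled scalar field by marching
#' tetrahedra: each voxel cell is split into 6 tetrahedra with a fixed
#' split shared by all cells, and each tetrahedron crossed by the level set
#' contributes one or two triangles whose vertices lie on tetrahedron edges
#' at the linear-interpolation root between the two bracketing samples.
#' Because every cut edge yields exactly one shared mesh vertex, the output
#' is watertight wherever the level set stays inside the sampled volume.
#' The per-tetrahedron case table has no ambiguous configurations, which is
#' why marching tetrahedra is used rather than classic marching cubes.
#'
#' Samples exactly equal to `c` are first perturbed by
#' `perturbRel * (field range)` so no triangle degenerates to zero area.
#' Vertices are returned in world coordinates
#' (`origin + index * spacing`). If `c` lies outside the sampled value
#' range the mesh is empty.
#'
#' @param grid a [VoxelGrid-class] with at least 2 samples per axis.
#' @param c the iso value (the level-set constant).
#' @param perturbRel relative perturbation applied to samples exactly equal
#'   to `c`; default `1e-9`.
#' @return A [TriMesh-class].
#' @examples
#' vol <- makeVolumePhantom("sphere_volume", dims = c(9, 9, 9),
#'                          spacing = 0.5)
#' extractIsosurface(vol$grid, c = 1)
#' @export
extractIsosurface <- function(grid, c, perturbRel = 1e-9) {
  stopifnot(is(grid, "VoxelGrid"))
  d <- dim(grid@values)
  if (any(d < 2L))
    stop("degenerate grid: isosurface extraction needs at least 2 samples per axis")
  vals <- grid@values
  rng <- max(vals) - min(vals)
  emptyMesh <- new("TriMesh",
                   vertices = matrix(numeric(0), 0L, 3L),
                   triangles = matrix(integer(0), 0L, 3L),
                   isoValue = as.numeric(c))
  if (c < min(vals) || c > max(vals) || rng == 0) return(emptyMesh)
  vals[vals == c] <- c + perturbRel * rng

  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  inside <- vals > c
  gid <- function(ix, iy, iz) ix + nx * ((iy - 1L) + ny * (iz - 1L))

  vertKey <- new.env(parent = emptyenv())
  verts <- list()
  nVert <- 0L
  tris <- list()
  nTri <- 0L

  ## Vertex on the tetrahedron edge between local cell corners iA and iB
  ## (1..8, bit-pattern order): the root of the cell's *trilinear*
  ## restriction along the edge, so every emitted vertex satisfies
  ## f(v) = c to root-finder precision. On axis-aligned edges the
  ## restriction is linear and this is the plain linear-interpolation
  ## root; on face diagonals the restriction is the face's bilinear form,
  ## shared with the neighbouring cell, so welding by edge key keeps the
  ## mesh watertight. The edge is parameterized from the lower global
  ## lattice id so both incident cells compute the identical root.
  edgeVertex <- function(iA, iB, f, g, a, base) {
    if (g[iA] > g[iB]) { tmp <- iA; iA <- iB; iB <- tmp }
    key <- paste0(g[iA], "_", g[iB])
    id <- vertKey[[key]]
    if (!is.null(id)) return(id)
    pA <- .CORNER_XYZ[iA, ]; pB <- .CORNER_XYZ[iB, ]
    dP <- pB - pA
    gfun <- function(t) {
      q <- pA + t * dP
      a[1] + a[2] * q[1] + a[3] * q[2] + a[4] * q[3] +
        a[5] * q[1] * q[2] + a[6] * q[2] * q[3] + a[7] * q[3] * q[1] +
        a[8] * q[1] * q[2] * q[3] - c
    }
    fA <- f[iA] - c; fB <- f[iB] - c
    ## axis-aligned edge (one coordinate varies): closed-form linear root
    t <- if (sum(dP != 0) == 1L) fA / (fA - fB)
    else stats::uniroot(gfun, c(0, 1), f.lower = fA, f.upper = fB,
                        tol = 1e-13)$root
    nVert <<- nVert + 1L
    verts[[nVert]] <<- grid@origin + (base + pA + t * dP) * grid@spacing
    vertKey[[key]] <- nVert
    nVert
  }

  emitTri <- function(v1, v2, v3, inPts, outPts) {
    ## orient the triangle so its normal points from the f > c side toward
    ## the f < c side (outward for a blob brighter than c)
    p1 <- verts[[v1]]; p2 <- verts[[v2]]; p3 <- verts[[v3]]
    nrm <- c(
      (p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
      (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
      (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    dir <- (colMeans(outPts) - colMeans(inPts)) * grid@spacing
    nTri <<- nTri + 1L
    tris[[nTri]] <<- if (sum(nrm * dir) >= 0) c(v1, v2, v3) else c(v1, v3, v2)
  }

  cornerOffsets <- .CORNER_XYZ  # 8 x 3, 0/1 offsets

  for (iz in seq_len(nz - 1L)) {
    for (iy in seq_len(ny - 1L)) {
      for (ix in seq_len(nx - 1L)) {
        cix <- ix + cornerOffsets[, 1L]
        ciy <- iy + cornerOffsets[, 2L]
        ciz <- iz + cornerOffsets[, 3L]
        idx <- cbind(cix, ciy, ciz)
        cin <- inside[idx]
        if (all(cin) || !any(cin)) next
        f <- vals[idx]
        g <- gid(cix, ciy, ciz)
        a <- cellCoeffs(f)@coeffs
        base <- c(ix, iy, iz) - 1L
        for (t in seq_len(6L)) {
          tv <- .CUBE_TETS[t, ]
          ti <- cin[tv]
          k <- sum(ti)
          if (k == 0L || k == 4L) next
          pts <- cbind(cix[tv], ciy[tv], ciz[tv])  # lattice coords, for orientation
          inPts <- pts[ti, , drop = FALSE]
          outPts <- pts[!ti, , drop = FALSE]
          if (k == 1L || k == 3L) {
            apex <- tv[if (k == 1L) which(ti) else which(!ti)]
            others <- tv[tv != apex]
            e <- vapply(others, function(o)
              edgeVertex(apex, o, f, g, a, base), integer(1))
            emitTri(e[1], e[2], e[3], inPts, outPts)
          } else {
            ii <- tv[ti]; oo <- tv[!ti]
            e11 <- edgeVertex(ii[1], oo[1], f, g, a, base)
            e12 <- edgeVertex(ii[1], oo[2], f, g, a, base)
            e21 <- edgeVertex(ii[2], oo[1], f, g, a, base)
            e22 <- edgeVertex(ii[2], oo[2], f, g, a, base)
            ## quad boundary e11 -> e21 -> e22 -> e12 (consecutive points
            ## share a tetrahedron face)
            emitTri(e11, e21, e22, inPts, outPts)
            emitTri(e11, e22, e12, inPts, outPts)
          }
        }
      }
    }
  }
  if (nVert == 0L) return(emptyMesh)
  new("TriMesh",
      vertices = do.call(rbind, verts),
      triangles = do.call(rbind, tris),
      isoValue = as.numeric(c))
}
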