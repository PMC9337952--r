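#' @include AllClasses.R
NULL

#' Accessors for the package's S4 containers
#'
#' Small generic accessors exposing the slots of [SurfacePatch-class],
#' [DepthImage-class], [FitResult-class], [VoxelGrid-class],
#' [TriMesh-class], [ImagePair-class] and [QualityReport-class] without
#' touching slots directly.
#'
#' @param object the container to query.
#' @return The corresponding component (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patchTier", function(object) standardGeneric("patchTier"))
#' @rdname accessors
#' @export
setGeneric("patchCoeffs", function(object) standardGeneric("patchCoeffs"))
#' @rdname accessors
#' @export
setGeneric("depthValues", function(object) standardGeneric("depthValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("fittedPatch", function(object) standardGeneric("fittedPatch"))
#' @rdname accessors
#' @export
setGeneric("fitChiSquare", function(object) standardGeneric("fitChiSquare"))
#' @rdname accessors
#' @export
setGeneric("medianSqResidual",
           function(object) standardGeneric("medianSqResidual"))
#' @rdname accessors
#' @export
setGeneric("inlierMask", function(object) standardGeneric("inlierMask"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("meshVertices", function(object) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("meshTriangles", function(object) standardGeneric("meshTriangles"))
#' @rdname accessors
#' @export
setGeneric("isoValue", function(object) standardGeneric("isoValue"))
#' @rdname accessors
#' @export
setGeneric("referenceImage", function(object) standardGeneric("referenceImage"))
#' @rdname accessors
#' @export
setGeneric("testImage", function(object) standardGeneric("testImage"))
#' @rdname accessors
#' @export
setGeneric("maxIntensity", function(object) standardGeneric("maxIntensity"))
#' @rdname accessors
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))
#' @rdname accessors
#' @export
setGeneric("cornerValues", function(object) standardGeneric("cornerValues"))
#' @rdname accessors
#' @export
setGeneric("cellCoefficients",
           function(object) standardGeneric("cellCoefficients"))

#' @rdname accessors
setMethod("patchTier", "SurfacePatch", function(object) object@tier)
#' @rdname accessors
setMethod("patchCoeffs", "SurfacePatch", function(object) object@coeffs)
#' @rdname accessors
setMethod("depthValues", "DepthImage", function(object) object@depths)
#' @rdname accessors
setMethod("validMask", "DepthImage", function(object) object@validMask)
#' @rdname accessors
setMethod("fittedPatch", "FitResult", function(object) object@patch)
#' @rdname accessors
setMethod("fitChiSquare", "FitResult", function(object) object@chiSquare)
#' @rdname accessors
setMethod("medianSqResidual", "FitResult",
          function(object) object@medianSqResidual)
#' @rdname accessors
setMethod("inlierMask", "FitResult", function(object) object@inlierMask)
#' @rdname accessors
setMethod("gridValues", "VoxelGrid", function(object) object@values)
#' @rdname accessors
setMethod("gridOrigin", "VoxelGrid", function(object) object@origin)
#' @rdname accessors
setMethod("gridSpacing", "VoxelGrid", function(object) object@spacing)
#' @rdname accessors
setMethod("meshVertices", "TriMesh", function(object) object@vertices)
#' @rdname accessors
setMethod("meshTriangles", "TriMesh", function(object) object@triangles)
#' @rdname accessors
setMethod("isoValue", "TriMesh", function(object) object@isoValue)
#' @rdname accessors
setMethod("referenceImage", "ImagePair", function(object) object@reference)
#' @rdname accessors
setMethod("testImage", "ImagePair", function(object) object@test)
#' @rdname accessors
setMethod("maxIntensity", "ImagePair", function(object) object@maxIntensity)
#' @rdname accessors
setMethod("reportTable", "QualityReport", function(object) object@table)
#' @rdname accessors
setMethod("cornerValues", "TrilinearCell", function(object) object@cornerValues)
#' @rdname accessors
setMethod("cellCoefficients", "TrilinearCell", function(object) object@coeffs)

.tierName <- c("plane", "bilinear", "quadratic", "cubic", "quartic")

setMethod("show", "SurfacePatch", function(object) {
  cat(sprintf("SurfacePatch tier %d (%s), %d coefficients\n",
              object@tier, .tierName[object@tier], length(object@coeffs)))
  cat("  coeffs:", paste(signif(object@coeffs, 6), collapse = " "), "\n")
})

setMethod("show", "DepthImage", function(object) {
  cat(sprintf("DepthImage %d x %d, %d/%d pixels valid\n",
              nrow(object@depths), ncol(object@depths),
              sum(object@validMask), length(object@validMask)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult: tier-%d patch, chi^2 = %.6g, median r^2 = %.6g, %d/%d inliers\n",
    object@patch@tier, object@chiSquare, object@medianSqResidual,
    sum(object@inlierMask), length(object@inlierMask)))
})

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelGrid %d x %d x %d, origin (%g, %g, %g), spacing (%g, %g, %g)\n",
              d[1], d[2], d[3], object@origin[1], object@origin[2],
              object@origin[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  value range [%g, %g]\n", min(object@values),
              max(object@values)))
})

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d triangles, iso value %g\n",
              nrow(object@vertices), nrow(object@triangles), object@isoValue))
})

setMethod("show", "ImagePair", function(object) {
  cat(sprintf("ImagePair %d x %d, MAX_I = %g\n", nrow(object@reference),
              ncol(object@reference), object@maxIntensity))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport (reference: %s)\n", object@referenceDescription))
  print(object@table[, c("algorithm", "psnr_db", "psnr_band", "ssim")],
        row.names = FALSE)
})
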