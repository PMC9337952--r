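#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## grayscale images: PNG / TIFF / PGM (P2 ascii and P5 binary), plus CSV grids

.imageFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = "png",
         tif = , tiff = "tiff",
         pgm = "pgm",
         csv = "csv",
         stop(sprintf("unsupported image format '.%s' (use png, tiff, pgm or csv)",
                      ext)))
}

.readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P5"))
    stop(sprintf("'%s' is not a PGM file (magic %s)", path, magic))
  ## tokenize header, skipping '#' comments
  txt <- rawToChar(raw)
  toks <- character(0)
  pos <- 3L          # byte position just past the magic
  nraw <- length(raw)
  while (length(toks) < 3L && pos <= nraw) {
    ch <- rawToChar(raw[pos])
    if (ch == "#") {                         # comment to end of line
      while (pos <= nraw && rawToChar(raw[pos]) != "\n") pos <- pos + 1L
    } else if (grepl("[[:space:]]", ch)) {
      pos <- pos + 1L
    } else {
      start <- pos
      while (pos <= nraw && !grepl("[[:space:]]", rawToChar(raw[pos])))
        pos <- pos + 1L
      toks <- c(toks, rawToChar(raw[start:(pos - 1L)]))
    }
  }
  if (length(toks) < 3L) stop("truncated PGM header")
  width <- as.integer(toks[1L]); height <- as.integer(toks[2L])
  maxval <- as.integer(toks[3L])
  if (is.na(maxval)) stop("malformed PGM header")
  if (magic == "P2") {
    vals <- scan(text = substring(txt, pos), what = integer(),
                 n = width * height, quiet = TRUE)
  } else {
    pos <- pos + 1L   # single whitespace byte after maxval
    vals <- as.integer(raw[pos:(pos + width * height - 1L)])
  }
  matrix(vals, nrow = height, ncol = width, byrow = TRUE)
}

.writePGM <- function(img, path, maxval = 255L) {
  img <- round(as.matrix(img))
  lines <- c("P2", sprintf("%d %d", ncol(img), nrow(img)),
             as.character(maxval),
             apply(img, 1L, paste, collapse = " "))
  writeLines(lines, path)
}

#' Read and write 8-bit grayscale images
#'
#' Reads a grayscale image from PNG, TIFF, PGM (ascii P2 or binary P5) or a
#' CSV grid into a numeric matrix on the 0..255 intensity scale
#' (row = image row). Color inputs are converted by channel averaging.
#' `writeGrayImage()` writes the same formats, clipping and rounding to
#' 8-bit.
#'
#' @param path file path; the extension selects the format.
#' @return `readGrayImage()`: a numeric matrix of intensities in 0..255.
#' @export
readGrayImage <- function(path) {
  fmt <- .imageFormat(path)
  if (fmt == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3L])),
                                           drop = FALSE], c(1L, 2L), mean)
    a * 255
  } else if (fmt == "tiff") {
    a <- tiff::readTIFF(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3L])),
                                           drop = FALSE], c(1L, 2L), mean)
    a * 255
  } else if (fmt == "pgm") {
    .readPGM(path) + 0
  } else {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
}

#' @rdname readGrayImage
#' @param img numeric matrix of intensities in 0..255.
#' @export
writeGrayImage <- function(img, path) {
  fmt <- .imageFormat(path)
  img <- pmin(pmax(as.matrix(img), 0), 255)
  if (fmt == "png") {
    png::writePNG(round(img) / 255, path)
  } else if (fmt == "tiff") {
    tiff::writeTIFF(round(img) / 255, path, bits.per.sample = 8L)
  } else if (fmt == "pgm") {
    .writePGM(img, path)
  } else {
    utils::write.table(img, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a depth image from an image file or CSV grid
#'
#' 8-bit image files are mapped to depths by the linear scale
#' `depth = offset + scale * pixel` (default: depth equals the pixel value,
#' units arbitrary); CSV grids are taken verbatim. An optional companion
#' mask image marks invalid pixels with 0.
#'
#' @param path depth image path (png/tiff/pgm/csv).
#' @param scale,offset linear map from pixel value to depth.
#' @param maskPath optional mask image path; pixels equal to 0 are invalid.
#' @return A [DepthImage-class].
#' @export
readDepthImage <- function(path, scale = 1, offset = 0, maskPath = NULL) {
  depths <- offset + scale * readGrayImage(path)
  mask <- if (is.null(maskPath)) NULL else readGrayImage(maskPath) != 0
  DepthImage(depths, mask)
}

## ---------------------------------------------------------------------------
## point sets

#' Read and write scattered 3D point sets as CSV
#'
#' CSV with header columns `x,y,z`. Malformed rows abort with a message
#' citing the first offending data row.
#'
#' @param path CSV file path.
#' @return `readPointSetCSV()`: an n x 3 numeric matrix with columns
#'   x, y, z.
#' @export
readPointSetCSV <- function(path) {
  df <- utils::read.csv(path, header = TRUE, colClasses = "character")
  if (!all(c("x", "y", "z") %in% names(df)))
    stop(sprintf("'%s': expected header columns x,y,z", path))
  m <- suppressWarnings(cbind(x = as.numeric(df$x), y = as.numeric(df$y),
                              z = as.numeric(df$z)))
  bad <- which(!stats::complete.cases(m))
  if (length(bad))
    stop(sprintf("'%s': malformed point at data row %d", path, bad[1L]))
  m
}

#' @rdname readPointSetCSV
#' @param points n x 3 matrix or data.frame of points.
#' @export
writePointSetCSV <- function(points, path) {
  m <- as.matrix(points)
  colnames(m) <- c("x", "y", "z")
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## surface patches and fit results as JSON

#' Serialize surface patches and fit results to JSON
#'
#' Patches are stored as `{"tier": t, "coeffs": [...]}`; fit results add
#' the chi-square, the median squared residual, and the (1-based) inlier
#' indices.
#'
#' @param patch a [SurfacePatch-class].
#' @param path output JSON path.
#' @return The read functions return the reconstructed object.
#' @export
writePatchJSON <- function(patch, path) {
  stopifnot(is(patch, "SurfacePatch"))
  jsonlite::write_json(list(tier = patch@tier, coeffs = patch@coeffs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePatchJSON
#' @export
readPatchJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  SurfacePatch(j$tier, j$coeffs)
}

#' @rdname writePatchJSON
#' @param fit a [FitResult-class].
#' @export
writeFitResultJSON <- function(fit, path) {
  stopifnot(is(fit, "FitResult"))
  jsonlite::write_json(
    list(patch = list(tier = fit@patch@tier, coeffs = fit@patch@coeffs),
         chi_square = fit@chiSquare,
         median_sq_residual = fit@medianSqResidual,
         inlier_indices = which(fit@inlierMask)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---------------------------------------------------------------------------
## voxel volumes: raw little-endian float32 + JSON sidecar

#' Read and write voxel volumes as raw float32 plus a JSON sidecar
#'
#' The lattice is stored as raw little-endian 32-bit floats in x-fastest
#' order with a JSON sidecar `{nx, ny, nz, origin, spacing}`; the sidecar
#' path defaults to `<rawPath>.json`.
#'
#' @param grid a [VoxelGrid-class].
#' @param rawPath path of the raw binary file.
#' @param jsonPath sidecar path.
#' @return `readVolume()`: a [VoxelGrid-class].
#' @export
writeVolume <- function(grid, rawPath, jsonPath = paste0(rawPath, ".json")) {
  stopifnot(is(grid, "VoxelGrid"))
  d <- dim(grid@values)
  con <- file(rawPath, "wb")
  on.exit(close(con))
  writeBin(as.vector(grid@values), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(nx = d[1L], ny = d[2L], nz = d[3L],
         origin = grid@origin, spacing = grid@spacing),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(rawPath)
}

#' @rdname writeVolume
#' @export
readVolume <- function(rawPath, jsonPath = paste0(rawPath, ".json")) {
  if (!file.exists(jsonPath))
    stop(sprintf("missing volume sidecar '%s'", jsonPath))
  h <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  n <- h$nx * h$ny * h$nz
  con <- file(rawPath, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  if (length(v) != n) stop(sprintf("'%s': truncated volume", rawPath))
  VoxelGrid(array(v, c(h$nx, h$ny, h$nz)), origin = h$origin,
            spacing = h$spacing)
}

## ---------------------------------------------------------------------------
## triangle meshes: OBJ and ascii PLY

#' Write a triangle mesh as Wavefront OBJ or ascii PLY
#'
#' @param mesh a [TriMesh-class].
#' @param path output path.
#' @return `readOBJ()` returns a [TriMesh-class] (iso value unknown, 0).
#' @export
writeOBJ <- function(mesh, path) {
  stopifnot(is(mesh, "TriMesh"))
  v <- mesh@vertices; f <- mesh@triangles
  lines <- c(
    sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
    sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeOBJ
#' @export
writePLY <- function(mesh, path) {
  stopifnot(is(mesh, "TriMesh"))
  v <- mesh@vertices; f <- mesh@triangles
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nrow(v)),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  lines <- c(header,
             sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
             sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeOBJ
#' @export
readOBJ <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  v <- if (length(vl))
    do.call(rbind, lapply(strsplit(vl, "[[:space:]]+"), function(t)
      as.numeric(t[2:4])))
  else matrix(numeric(0), 0L, 3L)
  f <- if (length(fl))
    do.call(rbind, lapply(strsplit(fl, "[[:space:]]+"), function(t)
      as.integer(sub("/.*", "", t[2:4]))))
  else matrix(integer(0), 0L, 3L)
  new("TriMesh", vertices = v, triangles = f, isoValue = 0)
}

## ---------------------------------------------------------------------------
## quality reports

#' Write a quality report as CSV and/or JSON
#'
#' The CSV carries the comparison-table column structure
#' `algorithm, psnr_db, psnr_band, ssim` (SSIM is unitless) plus the
#' `ssim_negative` flag.
#'
#' @param report a [QualityReport-class].
#' @param csvPath,jsonPath output paths; `NULL` skips that format.
#' @return The report, invisibly.
#' @export
writeQualityReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  stopifnot(is(report, "QualityReport"))
  if (!is.null(csvPath))
    utils::write.csv(report@table, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(reference = report@referenceDescription, rows = report@table),
      jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
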