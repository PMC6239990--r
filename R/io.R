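# plain array (integer/double) from an RNifti image object
stripImageAttributes <- function(img) {
  structure(as.vector(as.array(img)), dim = dim(img))
}

#' Read a volumetric image (NIfTI-1)
#'
#' Loads a 3-D NIfTI image and normalizes the world convention to RAS mm:
#' if the stored orientation is not RAS, the data array and affine are
#' reoriented at read time so no downstream code ever handles other
#' conventions. World locations of voxels are unchanged by reorientation.
#'
#' @param path file path to a `.nii` / `.nii.gz` image.
#' @return a [VolumeImage-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (RNifti::orientation(img) != "RAS") RNifti::orientation(img) <- "RAS"
  a <- unclass(RNifti::xform(img))
  attributes(a) <- list(dim = dim(a))
  dat <- stripImageAttributes(img)
  if (length(dim(dat)) == 4L && dim(dat)[4] == 1L)
    dat <- array(dat, dim = dim(dat)[1:3])
  if (length(dim(dat)) != 3L)
    stop("expected a 3-D payload, got dimensions ",
         paste(dim(dat), collapse = " x "))
  VolumeImage(dat, a)
}

#' Write a volumetric image (NIfTI-1)
#'
#' Integer arrays are stored as 32-bit integers (bit-exact round trip);
#' doubles as 64-bit floats.
#'
#' @param vol a [VolumeImage-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  dat <- vol@data
  datatype <- if (is.integer(dat)) "int32" else "double"
  img <- RNifti::asNifti(dat)
  # sform only: the quaternion qform cannot represent shears exactly
  RNifti::sform(img) <- structure(vol@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read / write a dense displacement field (vector NIfTI)
#'
#' The on-disk dialect is fixed: one 4-D NIfTI image whose three volumes are
#' the x, y, z world-mm displacement components, on the field's own grid.
#'
#' @param path file path.
#' @return [readField()]: a [VectorField-class].
#' @export
readField <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (RNifti::orientation(img) != "RAS") RNifti::orientation(img) <- "RAS"
  dat <- stripImageAttributes(img)
  d <- dim(dat)
  if (length(d) == 5L && d[4] == 1L) { # NIfTI displacement convention [x,y,z,1,3]
    dat <- array(dat, dim = d[c(1:3, 5)])
    d <- dim(dat)
  }
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement field must have exactly 3 components per node, got ",
         paste(d, collapse = " x "))
  a <- unclass(RNifti::xform(img))
  attributes(a) <- list(dim = dim(a))
  VectorField(dat, a)
}

#' @param field a [VectorField-class].
#' @rdname readField
#' @return [writeField()]: `path`, invisibly.
#' @export
writeField <- function(field, path) {
  img <- RNifti::asNifti(field@vectors)
  RNifti::sform(img) <- structure(field@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read / write a triangle mesh (plain text)
#'
#' Format: a header line `nVertices nFaces`, then `nVertices` rows of three
#' world coordinates (mm), then `nFaces` rows of three 0-based vertex
#' indices. Indices are converted to 1-based in memory.
#'
#' @param path file path.
#' @return [readMesh()]: a [TriangleMesh-class].
#' @export
readMesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- scan(text = lines[1], quiet = TRUE)
  if (length(hdr) != 2L || any(hdr < 0) || any(hdr != round(hdr)))
    stop("malformed mesh header: ", lines[1])
  nv <- hdr[1]; nf <- hdr[2]
  if (length(lines) < 1 + nv + nf) stop("truncated mesh file: ", path)
  vals <- scan(text = lines[2:(1 + nv)], quiet = TRUE)
  if (length(vals) != 3 * nv) stop("malformed vertex rows in ", path)
  v <- matrix(vals, nv, 3, byrow = TRUE)
  f <- matrix(0L, 0, 3)
  if (nf > 0) {
    fv <- scan(text = lines[(2 + nv):(1 + nv + nf)], quiet = TRUE)
    if (length(fv) != 3 * nf || any(fv != round(fv)))
      stop("malformed face rows in ", path)
    f <- matrix(as.integer(fv), nf, 3, byrow = TRUE) + 1L
    if (min(f) < 1L || max(f) > nv) stop("face indices out of range in ", path)
  }
  TriangleMesh(v, f)
}

#' @param mesh a [TriangleMesh-class].
#' @rdname readMesh
#' @return [writeMesh()]: `path`, invisibly.
#' @export
writeMesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mesh@vertices), nrow(mesh@faces)), con)
  writeLines(apply(format(mesh@vertices, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  if (nrow(mesh@faces) > 0)
    writeLines(apply(mesh@faces - 1L, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read / write per-vertex data (plain text)
#'
#' Format: a header line with the value count, then one value per row.
#' Integer payloads (label arrays) round-trip bit-exactly.
#'
#' @param path file path.
#' @return [readVertexData()]: a numeric or integer vector.
#' @export
readVertexData <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  n <- scan(text = lines[1], quiet = TRUE)
  if (length(n) != 1L || n != round(n)) stop("malformed header in ", path)
  vals <- scan(text = lines[-1], quiet = TRUE)
  if (length(vals) != n) stop("value count mismatch in ", path)
  if (all(vals == round(vals)) && max(abs(range(vals, finite = TRUE)), 0) <
      .Machine$integer.max && grepl("\\.labels?\\.", basename(path)))
    vals <- as.integer(vals)
  vals
}

#' @param values numeric or integer vector.
#' @rdname readVertexData
#' @export
writeVertexData <- function(values, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", length(values)), con)
  writeLines(format(values, digits = 17, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' Read / write a label table (CSV)
#'
#' Columns `id`, `name`, `color`; id 0 (background) never appears.
#'
#' @param path file path.
#' @return [readLabels()]: a [LabelTable-class].
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  e <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "name", "color") %in% names(e)))
    stop("label table must have columns id, name, color: ", path)
  LabelTable(e$id, e$name, e$color)
}

#' @param labels a [LabelTable-class].
#' @rdname readLabels
#' @export
writeLabels <- function(labels, path) {
  write.csv(labels@entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a 4 x 4 affine (whitespace text)
#'
#' @param path file path holding 4 rows of 4 numbers.
#' @return [readAffine()]: a 4 x 4 matrix.
#' @export
readAffine <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- scan(path, quiet = TRUE)
  if (length(vals) != 16L)
    stop("affine file must contain exactly 4 rows of 4 numbers: ", path)
  matrix(vals, 4, 4, byrow = TRUE)
}

#' @param affine 4 x 4 matrix.
#' @rdname readAffine
#' @export
writeAffine <- function(affine, path) {
  stopifnot(is4x4(affine))
  writeLines(apply(format(affine, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), path)
  invisible(path)
}

#' Serialize / load a transform chain as a text manifest
#'
#' The manifest lists one step per line, `affine <file>` or
#' `field <file> <source> <target>`, with file paths relative to the
#' manifest's directory.
#'
#' @param chain a [TransformChain-class].
#' @param path manifest path; step files are written next to it.
#' @export
writeChain <- function(chain, path) {
  dir <- dirname(path)
  base <- sub("\\.[^.]*$", "", basename(path))
  lines <- character(0)
  for (i in seq_along(chain@steps)) {
    s <- chain@steps[[i]]
    if (is(s, "AffineTransform")) {
      f <- sprintf("%s_step%02d.affine.txt", base, i)
      writeAffine(s@matrix, file.path(dir, f))
      lines <- c(lines, paste("affine", f))
    } else {
      f <- sprintf("%s_step%02d.field.nii.gz", base, i)
      writeField(s@field, file.path(dir, f))
      lines <- c(lines, paste("field", f, s@source, s@target))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeChain
#' @return [readChain()]: a [TransformChain-class].
#' @export
readChain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dir <- dirname(path)
  steps <- list()
  for (line in readLines(path)) {
    if (!nzchar(trimws(line))) next
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "affine") {
      steps <- c(steps, AffineTransform(readAffine(file.path(dir, tok[2]))))
    } else if (tok[1] == "field") {
      if (length(tok) < 4L) stop("malformed field line: ", line)
      steps <- c(steps, DenseTransform(readField(file.path(dir, tok[2])),
                                       tok[3], tok[4]))
    } else stop("unknown chain step type: ", tok[1])
  }
  transformChain(steps)
}
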