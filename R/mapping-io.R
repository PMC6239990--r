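mappingSidecar <- function(path, extra) {
  payload <- c(list(software = "regfuse",
                    version = as.character(packageVersion("regfuse"))),
               extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

#' Write / read a volume-to-surface mapping
#'
#' The mapping is a plain-text coordinate table (three columns, one row per
#' template vertex, world mm) with a JSON sidecar recording the cohort size,
#' subject ids and software version.
#'
#' @param m a [VolToSurfMapping-class].
#' @param path output table path (sidecar written at `<path>.json`).
#' @param subjects subject ids recorded in the sidecar.
#' @export
writeVolToSurfMapping <- function(m, path, subjects = character(0)) {
  write.table(format(m@coords, digits = 17, trim = TRUE,
                     scientific = FALSE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  mappingSidecar(paste0(path, ".json"),
                 list(kind = "vol2surf", nSubjects = m@nSubjects,
                      nVertices = nrow(m@coords), subjects = subjects))
  invisible(path)
}

#' @rdname writeVolToSurfMapping
#' @export
readVolToSurfMapping <- function(path) {
  vals <- as.matrix(read.table(path))
  dimnames(vals) <- NULL
  sidecar <- paste0(path, ".json")
  n <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE)$nSubjects
  else NA_integer_
  new("VolToSurfMapping", coords = vals, nSubjects = as.integer(n),
      nContributing = rep(as.integer(n), nrow(vals)))
}

#' Write / read a surface-to-volume mapping
#'
#' Serialized as NIfTI volumes under a common prefix: the 3-volume sphere
#' coordinate image, the final-vertex-index integer volume, the coverage
#' image and the two mask volumes, plus a JSON sidecar with thresholds,
#' cohort size, finalization state, subject ids and software version.
#'
#' @param m a [SurfToVolMapping-class].
#' @param prefix output path prefix.
#' @param subjects subject ids recorded in the sidecar.
#' @export
writeSurfToVolMapping <- function(m, prefix, subjects = character(0)) {
  d <- dim(m@coverage)
  sph <- m@sphereCoords
  sph[!is.finite(sph)] <- 0
  writeField(VectorField(sph, m@affine),
             paste0(prefix, "_coords.nii.gz"))
  writeVolume(VolumeImage(m@vertexIndex, m@affine),
              paste0(prefix, "_vertex.nii.gz"))
  writeVolume(VolumeImage(array(m@coverage, dim = d), m@affine),
              paste0(prefix, "_coverage.nii.gz"))
  writeVolume(VolumeImage(array(as.integer(m@tightMask), dim = d), m@affine),
              paste0(prefix, "_tight.nii.gz"))
  writeVolume(VolumeImage(array(as.integer(m@looseMask), dim = d), m@affine),
              paste0(prefix, "_loose.nii.gz"))
  mappingSidecar(paste0(prefix, ".json"),
                 list(kind = "surf2vol", nSubjects = m@nSubjects,
                      tightThresh = m@tightThresh,
                      looseThresh = m@looseThresh,
                      finalized = m@finalized, subjects = subjects))
  invisible(prefix)
}

#' @param templateSphere sphere mesh to re-attach on read (required to use
#'   a finalized mapping for projection).
#' @rdname writeSurfToVolMapping
#' @export
readSurfToVolMapping <- function(prefix, templateSphere = NULL) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  coords <- readField(paste0(prefix, "_coords.nii.gz"))
  vertex <- readVolume(paste0(prefix, "_vertex.nii.gz"))
  coverage <- readVolume(paste0(prefix, "_coverage.nii.gz"))
  tight <- readVolume(paste0(prefix, "_tight.nii.gz"))
  loose <- readVolume(paste0(prefix, "_loose.nii.gz"))
  d <- dim(coverage@data)
  sph <- coords@vectors
  vvi <- vertex@data
  storage.mode(vvi) <- "integer"
  lm <- loose@data != 0
  sphM <- matrix(sph, ncol = 3L)
  sphM[rowNorms(sphM) == 0, ] <- NA_real_
  if (is.null(templateSphere))
    templateSphere <- TriangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3))
  new("SurfToVolMapping", sphereCoords = array(sphM, dim = c(d, 3L)),
      coverage = array(as.double(coverage@data), dim = d),
      vertexIndex = vvi,
      tightMask = array(tight@data != 0, dim = d),
      looseMask = array(lm, dim = d),
      affine = coverage@affine,
      tightThresh = meta$tightThresh, looseThresh = meta$looseThresh,
      nSubjects = as.integer(meta$nSubjects),
      templateSphere = templateSphere,
      finalized = isTRUE(meta$finalized))
}
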