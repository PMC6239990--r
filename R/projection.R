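#' Project a volume onto the template surface
#'
#' Samples the volume at every template vertex's mapped volumetric
#' coordinate. Out-of-hull vertices get 0; their count is attached as
#' attribute `"nOutside"` and reported with a warning.
#'
#' @param vol a [VolumeImage-class] in the mapping's volume space.
#' @param m a [VolToSurfMapping-class].
#' @param interp `"trilinear"` (scalar data) or `"nearest"` (required for
#'   integer label volumes).
#' @return per-vertex vector (integer for label input).
#' @export
projectVolToSurf <- function(vol, m, interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  if (is.integer(vol@data) && interp != "nearest")
    stop("integer (label) volumes require interp = \"nearest\"")
  vox <- worldToVoxelPoints(m@coords, vol@affine)
  vals <- cppSampleGrid(as.double(vol@data), dim(vol@data), 1L, vox,
                        if (interp == "nearest") 1L else 0L)[, 1]
  nOut <- sum(!is.finite(vals))
  if (nOut > 0L) {
    vals[!is.finite(vals)] <- 0
    warning(nOut, " vertex coordinate(s) outside the volume; set to 0")
  }
  if (is.integer(vol@data)) vals <- as.integer(vals)
  attr(vals, "nOutside") <- nOut
  vals
}

#' Project template-surface data into the template volume
#'
#' Every loose-mask voxel receives the datum of its final template vertex
#' (`"nearest"`, required for labels) or the barycentric blend of its
#' averaged sphere coordinate on the template sphere (`"barycentric"`,
#' scalars only). Voxels outside the loose mask are 0; labels are never
#' invented.
#'
#' @param data per-template-vertex values.
#' @param m a finalized [SurfToVolMapping-class].
#' @param interp `"nearest"` or `"barycentric"`.
#' @return a [VolumeImage-class] on the mapping's grid.
#' @export
projectSurfToVol <- function(data, m, interp = c("nearest", "barycentric")) {
  interp <- match.arg(interp)
  if (!m@finalized) stop("mapping must be finalized (finalizeSurf2Vol)")
  if (length(data) != nrow(m@templateSphere@vertices))
    stop("data length must equal the template vertex count")
  if (isLabelData(data) && interp == "barycentric")
    stop("label data require interp = \"nearest\"")
  d <- dim(m@coverage)
  out <- numeric(prod(d))
  if (interp == "nearest") {
    idx <- which(m@looseMask & m@vertexIndex > 0L)
    out[idx] <- data[m@vertexIndex[idx]]
  } else {
    sph <- matrix(m@sphereCoords, ncol = 3L)
    idx <- which(m@looseMask & is.finite(sph[, 1]))
    loc <- barycentricLocate(m@templateSphere, sph[idx, , drop = FALSE])
    out[idx] <- applyBarycentric(as.double(data), m@templateSphere@faces, loc)
  }
  out <- array(out, dim = d)
  if (isLabelData(data)) storage.mode(out) <- "integer"
  VolumeImage(out, m@affine)
}

# Common-space check for parcellation lists.
sameSpace <- function(a, b) {
  if (!identical(a$type, b$type)) return(FALSE)
  if (a$type == "surface") return(identical(a$nVertices, b$nVertices))
  identical(a$dim, b$dim) && isTRUE(all.equal(a$affine, b$affine))
}

#' Per-label probabilistic maps from subject parcellations
#'
#' `probability(label, location)` is the fraction of subjects carrying that
#' label at the location. Label 0 (unlabeled) contributes no map, so
#' per-location sums equal 1 exactly where every subject is labeled.
#'
#' @param parcs list of [Parcellation-class] objects sharing one space and
#'   label table.
#' @return a [ProbabilisticMap-class].
#' @export
makeProbMaps <- function(parcs) {
  if (length(parcs) < 1L) stop("need at least one parcellation")
  space <- parcs[[1]]@space
  nloc <- length(parcs[[1]]@labels)
  for (p in parcs) {
    if (!sameSpace(p@space, space) || length(p@labels) != nloc)
      stop("parcellations must share one location space")
  }
  ids <- sort(parcs[[1]]@labelTable@entries$id)
  probs <- matrix(0, nloc, length(ids),
                  dimnames = list(NULL, as.character(ids)))
  for (p in parcs)
    for (j in seq_along(ids))
      probs[, j] <- probs[, j] + (p@labels == ids[j])
  probs <- probs / length(parcs)
  new("ProbabilisticMap", probs = probs, labels = as.integer(ids),
      labelTable = parcs[[1]]@labelTable, space = space,
      nSubjects = length(parcs))
}

#' Winner-takes-all parcellation from a probabilistic map
#'
#' Per location, the label with maximal probability; ties resolve to the
#' lowest label id. Unlabeled (0) never competes: a location gets 0 only
#' when every structure probability is 0.
#'
#' @param p a [ProbabilisticMap-class].
#' @return a [Parcellation-class].
#' @export
winnerTakesAll <- function(p) {
  ord <- order(p@labels)
  probs <- p@probs[, ord, drop = FALSE]
  ids <- p@labels[ord]
  best <- max.col(probs, ties.method = "first")
  lab <- ids[best]
  lab[probs[cbind(seq_len(nrow(probs)), best)] <= 0] <- 0L
  Parcellation(lab, p@labelTable, p@space)
}

#' Boundary vertices of a surface parcellation
#'
#' A vertex is on the boundary when any mesh neighbour carries a different
#' label; the set is invariant under label renaming.
#'
#' @param parc a surface [Parcellation-class].
#' @param mesh the surface [TriangleMesh-class].
#' @return logical per-vertex indicator.
#' @export
boundaryVertices <- function(parc, mesh) {
  if (!identical(parc@space$type, "surface"))
    stop("boundary extraction requires a surface parcellation")
  if (length(parc@labels) != nrow(mesh@vertices))
    stop("parcellation and mesh sizes differ")
  f <- mesh@faces
  lab <- parc@labels
  out <- logical(length(lab))
  for (cols in list(c(1, 2), c(2, 3), c(3, 1))) {
    diff <- lab[f[, cols[1]]] != lab[f[, cols[2]]]
    out[f[diff, cols[1]]] <- TRUE
    out[f[diff, cols[2]]] <- TRUE
  }
  out
}

#' Winner-takes-all parcellation with boundary indicator
#'
#' Thresholds a surface probabilistic map into its winner-takes-all
#' parcellation and attaches the per-vertex boundary indicator (attribute
#' `"boundary"`) for boundary rendering.
#'
#' @param p a surface [ProbabilisticMap-class].
#' @param mesh the surface mesh.
#' @return a [Parcellation-class] with attribute `"boundary"`.
#' @export
thresholdBoundaries <- function(p, mesh) {
  parc <- winnerTakesAll(p)
  attr(parc, "boundary") <- boundaryVertices(parc, mesh)
  parc
}
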