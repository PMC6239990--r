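#' Volumetric image with a voxel-to-world affine
#'
#' A 3-D scalar or integer grid together with the 4 x 4 affine mapping
#' 0-based voxel indices to world coordinates (mm, RAS). All world
#' coordinates in the package are RAS mm; readers normalize orientation at
#' the boundary so downstream code never reorients.
#'
#' @slot data 3-D array (double or integer).
#' @slot affine 4 x 4 voxel-to-world matrix (mm, RAS), invertible.
#' @export
setClass("VolumeImage", representation(data = "array", affine = "matrix"))

setValidity("VolumeImage", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (!is4x4(object@affine)) return("affine must be a finite 4 x 4 matrix")
  if (!isInvertible(object@affine)) return("affine must be invertible")
  TRUE
})

#' @param data 3-D array.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @rdname VolumeImage-class
#' @export
VolumeImage <- function(data, affine = diag(4)) {
  new("VolumeImage", data = data, affine = affine)
}

#' Dense displacement field on its own grid
#'
#' Vector image holding a world-space displacement (mm) at every node of a
#' reference grid. Displacements are world-mm vectors sampled on the field's
#' own grid; off-node values are obtained by component-wise trilinear
#' interpolation.
#'
#' @slot vectors 4-D array `[nx, ny, nz, 3]` of world-mm displacements.
#' @slot affine 4 x 4 voxel-to-world matrix of the field's grid.
#' @export
setClass("VectorField", representation(vectors = "array", affine = "matrix"))

setValidity("VectorField", function(object) {
  d <- dim(object@vectors)
  if (length(d) != 4L || d[4] != 3L)
    return("vectors must be a 4-D array with 3 components per node")
  if (!is4x4(object@affine)) return("affine must be a finite 4 x 4 matrix")
  if (!isInvertible(object@affine)) return("affine must be invertible")
  TRUE
})

#' @param vectors 4-D array `[nx, ny, nz, 3]`.
#' @param affine 4 x 4 voxel-to-world matrix of the field grid.
#' @rdname VectorField-class
#' @export
VectorField <- function(vectors, affine = diag(4)) {
  new("VectorField", vectors = vectors, affine = affine)
}

#' Triangle mesh in world coordinates
#'
#' @slot vertices n x 3 matrix of world coordinates (mm).
#' @slot faces m x 3 integer matrix of 1-based vertex indices (0-based on
#'   disk; converted at the I/O boundary).
#' @export
setClass("TriangleMesh", representation(vertices = "matrix", faces = "matrix"))

setValidity("TriangleMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must have 3 columns")
  if (ncol(object@faces) != 3L) return("faces must have 3 columns")
  if (nrow(object@faces) > 0) {
    f <- object@faces
    if (min(f) < 1L || max(f) > nrow(object@vertices))
      return("face indices out of range")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      return("degenerate face (repeated vertex index)")
  }
  TRUE
})

#' @param vertices n x 3 matrix.
#' @param faces m x 3 matrix of 1-based indices.
#' @rdname TriangleMesh-class
#' @export
TriangleMesh <- function(vertices, faces) {
  vertices <- asPoints(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  new("TriangleMesh", vertices = vertices, faces = faces)
}

#' Label table
#'
#' Maps positive integer label ids to structure names and colors. Label 0 is
#' reserved for background/unlabeled everywhere and never appears as a named
#' structure.
#'
#' @slot entries data.frame with columns `id`, `name`, `color`.
#' @export
setClass("LabelTable", representation(entries = "data.frame"))

setValidity("LabelTable", function(object) {
  e <- object@entries
  if (!all(c("id", "name", "color") %in% names(e)))
    return("entries must have columns id, name, color")
  if (anyDuplicated(e$id)) return("label ids must be unique")
  if (any(e$id <= 0)) return("label ids must be positive (0 is background)")
  TRUE
})

#' @param id integer vector of positive label ids.
#' @param name character vector of structure names.
#' @param color character vector of colors (any string encoding).
#' @rdname LabelTable-class
#' @export
LabelTable <- function(id, name = paste0("label_", id),
                       color = rep("#808080", length(id))) {
  new("LabelTable", entries = data.frame(id = as.integer(id),
                                         name = as.character(name),
                                         color = as.character(color),
                                         stringsAsFactors = FALSE))
}

#' World-to-world affine transform
#'
#' @slot matrix 4 x 4 matrix with last row (0, 0, 0, 1).
#' @slot source,target optional space names ("" = unspecified).
#' @export
setClass("AffineTransform", representation(matrix = "matrix",
                                           source = "character",
                                           target = "character"))

setValidity("AffineTransform", function(object) {
  if (!is4x4(object@matrix)) return("matrix must be a finite 4 x 4 matrix")
  if (!isTRUE(all.equal(object@matrix[4, ], c(0, 0, 0, 1))))
    return("last row must be (0, 0, 0, 1)")
  if (!isInvertible(object@matrix)) return("matrix must be invertible")
  TRUE
})

#' @param matrix 4 x 4 matrix.
#' @rdname AffineTransform-class
#' @export
AffineTransform <- function(matrix, source = "", target = "") {
  matrix <- unname(as.matrix(matrix))
  new("AffineTransform", matrix = matrix, source = source, target = target)
}

#' Dense nonlinear transform with direction tags
#'
#' Maps points from its named source space to its named target space as
#' `x -> x + u(x)` with `u` the displacement field sampled trilinearly.
#'
#' @slot field a [VectorField-class].
#' @slot source,target non-empty space names.
#' @export
setClass("DenseTransform", representation(field = "VectorField",
                                          source = "character",
                                          target = "character"))

setValidity("DenseTransform", function(object) {
  if (!nzchar(object@source) || !nzchar(object@target))
    return("source and target space names must be non-empty")
  if (!all(is.finite(object@field@vectors)))
    return("field must be finite everywhere")
  TRUE
})

#' @param field a [VectorField-class].
#' @rdname DenseTransform-class
#' @export
DenseTransform <- function(field, source, target) {
  new("DenseTransform", field = field, source = source, target = target)
}

#' Ordered chain of transforms
#'
#' Steps are applied in order; adjacent space names must be consistent
#' (the target of step i equals the source of step i + 1, with "" acting as
#' a wildcard for untagged affines). Composition is lazy: chains are applied
#' point-wise; [bakeChain()] exports a single dense field on a stated grid.
#'
#' @slot steps list of [AffineTransform-class] / [DenseTransform-class].
#' @export
setClass("TransformChain", representation(steps = "list"))

setValidity("TransformChain", function(object) {
  for (s in object@steps)
    if (!is(s, "AffineTransform") && !is(s, "DenseTransform"))
      return("steps must be AffineTransform or DenseTransform objects")
  prev <- ""
  for (s in object@steps) {
    src <- s@source
    if (nzchar(prev) && nzchar(src) && prev != src)
      return(sprintf("inconsistent chain: step source '%s' != previous target '%s'",
                     src, prev))
    if (nzchar(s@target)) prev <- s@target else prev <- ""
  }
  TRUE
})

#' @param ... transforms, in application order.
#' @rdname TransformChain-class
#' @export
transformChain <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && is.list(steps[[1]]) && !is(steps[[1]], "AffineTransform") &&
      !is(steps[[1]], "DenseTransform"))
    steps <- steps[[1]]
  new("TransformChain", steps = steps)
}

#' Spherical surface registration of one subject
#'
#' Per-vertex positions of a subject's anatomical mesh on the common unit
#' sphere, plus the shared template sphere. Sphere positions are normalized
#' to unit radius at construction (100 mm-radius conventions are accepted
#' and rescaled).
#'
#' @slot subjectMesh the subject's anatomical mid-thickness mesh (world mm).
#' @slot sphereCoords n x 3 unit vectors, one per subject vertex.
#' @slot templateSphere the common template sphere mesh (unit radius).
#' @export
setClass("SphericalRegistration",
         representation(subjectMesh = "TriangleMesh",
                        sphereCoords = "matrix",
                        templateSphere = "TriangleMesh"))

setValidity("SphericalRegistration", function(object) {
  if (nrow(object@sphereCoords) != nrow(object@subjectMesh@vertices))
    return("one sphere position is required per subject vertex")
  n <- rowNorms(object@sphereCoords)
  if (any(abs(n - 1) > 1e-6))
    return("sphere positions must be unit vectors (within 1e-6)")
  TRUE
})

#' @param subjectMesh,sphereCoords,templateSphere see slots.
#' @rdname SphericalRegistration-class
#' @export
SphericalRegistration <- function(subjectMesh, sphereCoords, templateSphere) {
  sphereCoords <- asPoints(sphereCoords)
  n <- rowNorms(sphereCoords)
  if (any(n == 0)) stop("zero-norm sphere position")
  sphereCoords <- sphereCoords / n
  new("SphericalRegistration", subjectMesh = subjectMesh,
      sphereCoords = sphereCoords, templateSphere = templateSphere)
}

#' Per-subject registration bundle
#'
#' Everything registration fusion needs from one subject: the chain mapping
#' template-volume points into the subject's anatomical space (pull-back
#' direction for resampling subject images onto the template grid), its
#' inverse (for pushing surface vertices into template space), the spherical
#' surface registration, and the subject-space cortical ribbon mask.
#'
#' @slot id subject identifier.
#' @slot volChain [TransformChain-class], template volume -> subject.
#' @slot invVolChain [TransformChain-class], subject -> template volume.
#' @slot reg [SphericalRegistration-class].
#' @slot ribbonMask binary [VolumeImage-class] in subject space.
#' @export
setClass("SubjectBundle",
         representation(id = "character", volChain = "TransformChain",
                        invVolChain = "TransformChain",
                        reg = "SphericalRegistration",
                        ribbonMask = "VolumeImage"))

setValidity("SubjectBundle", function(object) {
  if (sum(object@ribbonMask@data != 0) == 0L)
    return("ribbon mask is empty")
  TRUE
})

#' @param id,volChain,invVolChain,reg,ribbonMask see slots.
#' @rdname SubjectBundle-class
#' @export
SubjectBundle <- function(id, volChain, invVolChain, reg, ribbonMask) {
  new("SubjectBundle", id = as.character(id), volChain = volChain,
      invVolChain = invVolChain, reg = reg, ribbonMask = ribbonMask)
}

#' Volume-to-surface mapping
#'
#' For every template-surface vertex, the cohort-averaged template-volume
#' world coordinate (mm).
#'
#' @slot coords V x 3 matrix of template-volume world coordinates.
#' @slot nSubjects cohort size used in the average.
#' @slot nContributing per-vertex count of subjects that contributed.
#' @export
setClass("VolToSurfMapping",
         representation(coords = "matrix", nSubjects = "integer",
                        nContributing = "integer"))

setValidity("VolToSurfMapping", function(object) {
  if (ncol(object@coords) != 3L) return("coords must have 3 columns")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (length(object@nContributing) != nrow(object@coords))
    return("nContributing must have one entry per vertex")
  TRUE
})

#' Surface-to-volume mapping
#'
#' Per template-grid voxel: the cohort-averaged common-sphere coordinate
#' (renormalized to unit length), the fraction of subjects whose cortex
#' covered the voxel, the final template vertex index (0 until
#' [finalizeSurf2Vol()]), and the tight/loose coverage masks.
#'
#' @slot sphereCoords 4-D array `[nx, ny, nz, 3]` (NA where no coverage).
#' @slot coverage 3-D array of coverage fractions in `[0, 1]`.
#' @slot vertexIndex 3-D integer array of final vertex indices (0 = none).
#' @slot tightMask,looseMask 3-D logical arrays; tight is a subset of loose.
#' @slot affine template-grid voxel-to-world matrix.
#' @slot tightThresh,looseThresh coverage thresholds used (compared with >=).
#' @slot nSubjects cohort size.
#' @slot templateSphere template sphere mesh (set at finalization).
#' @slot finalized whether final vertex indices have been assigned.
#' @export
setClass("SurfToVolMapping",
         representation(sphereCoords = "array", coverage = "array",
                        vertexIndex = "array", tightMask = "array",
                        looseMask = "array", affine = "matrix",
                        tightThresh = "numeric", looseThresh = "numeric",
                        nSubjects = "integer",
                        templateSphere = "TriangleMesh",
                        finalized = "logical"))

setValidity("SurfToVolMapping", function(object) {
  if (any(object@tightMask & !object@looseMask))
    return("tight mask must be a subset of the loose mask")
  cov <- object@coverage
  if (any(cov < -1e-12 | cov > 1 + 1e-12))
    return("coverage fractions must lie in [0, 1]")
  if (object@looseThresh > object@tightThresh)
    return("loose threshold must not exceed tight threshold")
  TRUE
})

#' Per-location label probabilities
#'
#' @slot probs n x L matrix, one column per label, each value in `[0, 1]`,
#'   per-location sums at most 1.
#' @slot labels integer label ids (ascending), matching `probs` columns.
#' @slot labelTable a [LabelTable-class].
#' @slot space list describing the location domain: `list(type = "surface",
#'   nVertices =)` or `list(type = "volume", dim =, affine =)`.
#' @slot nSubjects number of subjects averaged.
#' @export
setClass("ProbabilisticMap",
         representation(probs = "matrix", labels = "integer",
                        labelTable = "LabelTable", space = "list",
                        nSubjects = "integer"))

setValidity("ProbabilisticMap", function(object) {
  p <- object@probs
  if (ncol(p) != length(object@labels))
    return("one probability column per label is required")
  if (any(p < -1e-9 | p > 1 + 1e-9)) return("probabilities must be in [0, 1]")
  if (any(rowSums(p) > 1 + 1e-9))
    return("per-location probability sums must not exceed 1")
  TRUE
})

#' Hard parcellation
#'
#' @slot labels integer vector of per-location labels (0 = unlabeled).
#' @slot labelTable a [LabelTable-class].
#' @slot space location domain descriptor (see [ProbabilisticMap-class]).
#' @export
setClass("Parcellation",
         representation(labels = "integer", labelTable = "LabelTable",
                        space = "list"))

setValidity("Parcellation", function(object) {
  ok <- c(0L, object@labelTable@entries$id)
  if (!all(object@labels %in% ok))
    return("labels must appear in the label table (or be 0)")
  TRUE
})

#' @param labels,labelTable,space see slots.
#' @rdname Parcellation-class
#' @export
Parcellation <- function(labels, labelTable, space) {
  new("Parcellation", labels = as.integer(labels), labelTable = labelTable,
      space = space)
}

#' Synthetic shell-phantom specification
#'
#' The phantom world is a spherical cortical-ribbon shell centered in a
#' cubic grid, with an icosphere mid-thickness surface and an angular
#' parcellation. Defaults give a 48 mm, 1 mm-isotropic grid with a 14-18 mm
#' shell, a level-3 icosphere (642 vertices) and 16 parcels.
#'
#' @slot gridShape grid size per axis (voxels).
#' @slot voxelSize isotropic voxel size (mm).
#' @slot rIn,rOut inner/outer shell radii (mm).
#' @slot nParcels number of angular parcels (>= 2).
#' @slot nSubjects cohort size.
#' @slot amplitude per-subject warp amplitude: max displacement norm (mm).
#' @slot jitterDeg spherical-registration jitter budget (degrees).
#' @slot seed master seed; all draws are keyed by (seed, subject, name).
#' @slot subdivisions icosphere subdivision level.
#' @slot recenter recenter the cohort-mean displacement to zero at the
#'   control nodes so the template is the cohort's true center.
#' @export
setClass("PhantomSpec",
         representation(gridShape = "integer", voxelSize = "numeric",
                        rIn = "numeric", rOut = "numeric",
                        nParcels = "integer", nSubjects = "integer",
                        amplitude = "numeric", jitterDeg = "numeric",
                        seed = "integer", subdivisions = "integer",
                        recenter = "logical"))

setValidity("PhantomSpec", function(object) {
  halfExtent <- (object@gridShape - 1) * object@voxelSize / 2
  if (!(0 < object@rIn && object@rIn < object@rOut))
    return("need 0 < rIn < rOut")
  if (object@rOut >= halfExtent)
    return("rOut must be smaller than the grid half-extent")
  if (object@nParcels < 2L) return("need at least 2 parcels")
  if (object@amplitude < 0) return("amplitude must be non-negative")
  if (object@jitterDeg < 0) return("jitter must be non-negative")
  if (object@nSubjects < 1L) return("need at least 1 subject")
  TRUE
})

#' @param gridShape,voxelSize,rIn,rOut,nParcels,nSubjects,amplitude
#'   see slots.
#' @param jitterDeg,seed,subdivisions,recenter see slots.
#' @rdname PhantomSpec-class
#' @export
phantomSpec <- function(gridShape = 48L, voxelSize = 1, rIn = 14, rOut = 18,
                        nParcels = 16L, nSubjects = 8L, amplitude = 1,
                        jitterDeg = 2, seed = 1L, subdivisions = 3L,
                        recenter = TRUE) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = as.numeric(voxelSize), rIn = as.numeric(rIn),
      rOut = as.numeric(rOut), nParcels = as.integer(nParcels),
      nSubjects = as.integer(nSubjects), amplitude = as.numeric(amplitude),
      jitterDeg = as.numeric(jitterDeg), seed = as.integer(seed),
      subdivisions = as.integer(subdivisions), recenter = recenter)
}
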