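#' Accessors for regfuse data objects
#'
#' Slot access goes through these accessors rather than `@`.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setGeneric("voxelToWorld", function(x) standardGeneric("voxelToWorld"))
#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname accessors
#' @export
setGeneric("sphereCoords", function(x) standardGeneric("sphereCoords"))
#' @rdname accessors
#' @export
setGeneric("mappingCoords", function(x) standardGeneric("mappingCoords"))
#' @rdname accessors
#' @export
setGeneric("coverageFraction", function(x) standardGeneric("coverageFraction"))
#' @rdname accessors
#' @export
setGeneric("tightMask", function(x) standardGeneric("tightMask"))
#' @rdname accessors
#' @export
setGeneric("looseMask", function(x) standardGeneric("looseMask"))
#' @rdname accessors
#' @export
setGeneric("finalVertices", function(x) standardGeneric("finalVertices"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setGeneric("probValues", function(x) standardGeneric("probValues"))
#' @rdname accessors
#' @export
setGeneric("parcelLabels", function(x) standardGeneric("parcelLabels"))
#' @rdname accessors
#' @export
setGeneric("labelIds", function(x) standardGeneric("labelIds"))
#' @rdname accessors
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))

#' @rdname accessors
#' @export
setMethod("imgData", "VolumeImage", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("imgData", "VectorField", function(x) x@vectors)
#' @rdname accessors
#' @export
setMethod("voxelToWorld", "VolumeImage", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("voxelToWorld", "VectorField", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("voxelToWorld", "SurfToVolMapping", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)
#' @rdname accessors
#' @export
setMethod("sphereCoords", "SphericalRegistration", function(x) x@sphereCoords)
#' @rdname accessors
#' @export
setMethod("sphereCoords", "SurfToVolMapping", function(x) x@sphereCoords)
#' @rdname accessors
#' @export
setMethod("mappingCoords", "VolToSurfMapping", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("coverageFraction", "SurfToVolMapping", function(x) x@coverage)
#' @rdname accessors
#' @export
setMethod("tightMask", "SurfToVolMapping", function(x) x@tightMask)
#' @rdname accessors
#' @export
setMethod("looseMask", "SurfToVolMapping", function(x) x@looseMask)
#' @rdname accessors
#' @export
setMethod("finalVertices", "SurfToVolMapping", function(x) x@vertexIndex)
#' @rdname accessors
#' @export
setMethod("nSubjects", "VolToSurfMapping", function(x) x@nSubjects)
#' @rdname accessors
#' @export
setMethod("nSubjects", "SurfToVolMapping", function(x) x@nSubjects)
#' @rdname accessors
#' @export
setMethod("nSubjects", "ProbabilisticMap", function(x) x@nSubjects)
#' @rdname accessors
#' @export
setMethod("probValues", "ProbabilisticMap", function(x) x@probs)
#' @rdname accessors
#' @export
setMethod("parcelLabels", "Parcellation", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("labelIds", "ProbabilisticMap", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("labelIds", "LabelTable", function(x) x@entries$id)
#' @rdname accessors
#' @export
setMethod("labelTable", "ProbabilisticMap", function(x) x@labelTable)
#' @rdname accessors
#' @export
setMethod("labelTable", "Parcellation", function(x) x@labelTable)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeImage: %d x %d x %d %s voxels\n", d[1], d[2], d[3],
              typeof(object@data)))
  cat("voxel-to-world (RAS mm):\n")
  print(round(object@affine, 4))
})

setMethod("show", "VectorField", function(object) {
  d <- dim(object@vectors)
  cat(sprintf("VectorField: %d x %d x %d nodes, max |u| = %.3f mm\n",
              d[1], d[2], d[3],
              sqrt(max(rowSums(matrix(object@vectors, ncol = 3L)^2)))))
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (world -> world, mm)\n")
  print(round(object@matrix, 4))
})

setMethod("show", "DenseTransform", function(object) {
  cat(sprintf("DenseTransform: %s -> %s\n", object@source, object@target))
  show(object@field)
})

setMethod("show", "TransformChain", function(object) {
  cat(sprintf("TransformChain with %d step(s)\n", length(object@steps)))
  for (s in object@steps) {
    if (is(s, "AffineTransform")) cat("  - affine\n")
    else cat(sprintf("  - dense %s -> %s\n", s@source, s@target))
  }
})

setMethod("show", "SphericalRegistration", function(object) {
  cat(sprintf("SphericalRegistration: %d subject vertices on the unit sphere\n",
              nrow(object@sphereCoords)))
})

setMethod("show", "SubjectBundle", function(object) {
  cat(sprintf("SubjectBundle '%s': %d ribbon voxels, %d surface vertices\n",
              object@id, sum(object@ribbonMask@data != 0),
              nrow(object@reg@subjectMesh@vertices)))
})

setMethod("show", "VolToSurfMapping", function(object) {
  cat(sprintf("VolToSurfMapping: %d vertices, averaged over %d subject(s)\n",
              nrow(object@coords), object@nSubjects))
})

setMethod("show", "SurfToVolMapping", function(object) {
  cat(sprintf(paste0("SurfToVolMapping: %d tight / %d loose voxels ",
                     "(thresholds %.2f / %.2f, N = %d)%s\n"),
              sum(object@tightMask), sum(object@looseMask),
              object@tightThresh, object@looseThresh, object@nSubjects,
              if (object@finalized) ", finalized" else ""))
})

setMethod("show", "ProbabilisticMap", function(object) {
  cat(sprintf("ProbabilisticMap: %d locations (%s) x %d labels, N = %d\n",
              nrow(object@probs), object@space$type, ncol(object@probs),
              object@nSubjects))
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d locations (%s), %d labels (+ background)\n",
              length(object@labels), object@space$type,
              length(unique(object@labels[object@labels != 0L]))))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %d^3 grid @ %g mm, shell %g-%g mm, ",
                     "%d parcels, N = %d, a = %g mm, jitter = %g deg, ",
                     "seed = %d\n"),
              object@gridShape, object@voxelSize, object@rIn, object@rOut,
              object@nParcels, object@nSubjects, object@amplitude,
              object@jitterDeg, object@seed))
})
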