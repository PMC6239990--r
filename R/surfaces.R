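#' Nearest mesh vertex per query point
#'
#' Euclidean-nearest vertex; ties resolve to the lowest vertex index.
#'
#' @param mesh a [TriangleMesh-class].
#' @param points n x 3 matrix of points.
#' @return integer vector of 1-based vertex indices.
#' @export
nearestVertex <- function(mesh, points) {
  if (nrow(mesh@vertices) == 0L) stop("mesh has no vertices")
  cppNearestPoint(mesh@vertices, asPoints(points))
}

# Barycentric weights of query directions with respect to given faces,
# using ray-through-origin (gnomonic) coordinates: w solves
# [v1 v2 v3] w = q up to scale, via signed volumes. Vectorized over rows.
rayBarycentric <- function(V, F, faceIdx, Q) {
  v1 <- V[F[faceIdx, 1], , drop = FALSE]
  v2 <- V[F[faceIdx, 2], , drop = FALSE]
  v3 <- V[F[faceIdx, 3], , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  dt <- function(a, b) rowSums(a * b)
  d0 <- dt(v1, cr(v2, v3))
  w1 <- dt(Q, cr(v2, v3)) / d0
  w2 <- dt(Q, cr(v3, v1)) / d0  # det(v1, q, v3) = q . (v3 x v1)
  w3 <- dt(Q, cr(v1, v2)) / d0
  cbind(w1, w2, w3)
}

#' Locate points on a closed sphere mesh
#'
#' Finds, for each unit query direction, the spherical triangle containing
#' it, by gnomonic projection onto candidate face planes (faces incident to
#' the nearest vertex, then an exhaustive fallback). Weights are clipped at
#' `-1e-9`, set to zero if slightly negative, and renormalized to sum 1.
#'
#' @param sphere a closed [TriangleMesh-class] on the sphere.
#' @param points n x 3 matrix; normalized to unit length internally.
#' @return list with `face` (integer vector) and `weights` (n x 3 matrix);
#'   weight column j refers to face vertex j.
#' @export
barycentricLocate <- function(sphere, points) {
  Q <- normalizeRows(asPoints(points))
  V <- normalizeRows(sphere@vertices)
  F <- sphere@faces
  n <- nrow(Q)
  inc <- vertexFaceIncidence(sphere)
  nn <- cppNearestPoint(V, Q)
  cand <- inc[nn, , drop = FALSE]
  face <- integer(n)
  weights <- matrix(NA_real_, n, 3)
  unresolved <- rep(TRUE, n)
  for (j in seq_len(ncol(cand))) {
    idx <- which(unresolved & !is.na(cand[, j]))
    if (!length(idx)) next
    fj <- cand[idx, j]
    w <- rayBarycentric(V, F, fj, Q[idx, , drop = FALSE])
    ok <- rowSums(w >= -1e-9) == 3L & is.finite(rowSums(w))
    hit <- idx[ok]
    face[hit] <- fj[ok]
    weights[hit, ] <- w[ok, , drop = FALSE]
    unresolved[hit] <- FALSE
  }
  # rare fallback: scan all faces, keep the one with the largest min weight
  for (i in which(unresolved)) {
    w <- rayBarycentric(V, F, seq_len(nrow(F)),
                        Q[rep(i, nrow(F)), , drop = FALSE])
    score <- apply(w, 1, min)
    score[!is.finite(score)] <- -Inf
    best <- which.max(score)
    if (!is.finite(score[best]) || score[best] < -0.1)
      stop("no containing face found for query point ", i)
    face[i] <- best
    weights[i, ] <- w[best, ]
  }
  weights[weights < 0] <- 0
  weights <- weights / rowSums(weights)
  list(face = face, weights = weights)
}

# Interpolate per-vertex values at located positions.
applyBarycentric <- function(values, faces, loc) {
  f <- faces[loc$face, , drop = FALSE]
  if (is.null(dim(values))) {
    loc$weights[, 1] * values[f[, 1]] + loc$weights[, 2] * values[f[, 2]] +
      loc$weights[, 3] * values[f[, 3]]
  } else {
    loc$weights[, 1] * values[f[, 1], , drop = FALSE] +
      loc$weights[, 2] * values[f[, 2], , drop = FALSE] +
      loc$weights[, 3] * values[f[, 3], , drop = FALSE]
  }
}

# The subject's mesh topology with its vertices moved to their common-sphere
# positions.
subjectSphereMesh <- function(reg) {
  TriangleMesh(reg@sphereCoords, reg@subjectMesh@faces)
}

#' Resample subject surface data onto the template surface
#'
#' Each template-sphere vertex is located among the subject's sphere
#' coordinates; scalars are interpolated barycentrically, labels take the
#' nearest subject vertex's value.
#'
#' @param reg a [SphericalRegistration-class].
#' @param subjectData per-subject-vertex values (numeric scalars, or an
#'   integer label vector with `interp = "nearest"`).
#' @param interp `"barycentric"` or `"nearest"`.
#' @return one value per template-sphere vertex.
#' @export
resampleToTemplate <- function(reg, subjectData,
                               interp = c("barycentric", "nearest")) {
  interp <- match.arg(interp)
  if (length(subjectData) != nrow(reg@sphereCoords))
    stop("data length must equal the subject vertex count")
  if (isLabelData(subjectData) && interp == "barycentric")
    stop("label data require interp = \"nearest\"")
  tv <- normalizeRows(reg@templateSphere@vertices)
  if (interp == "nearest") {
    nn <- cppNearestPoint(reg@sphereCoords, tv)
    return(subjectData[nn])
  }
  loc <- barycentricLocate(subjectSphereMesh(reg), tv)
  applyBarycentric(subjectData, reg@subjectMesh@faces, loc)
}

#' Map template vertices into a subject's anatomical space
#'
#' Each requested template-sphere vertex is located among the subject's
#' sphere coordinates; its barycentric weights are applied to the subject's
#' anatomical vertex positions, yielding the corresponding subject-space
#' world point on the subject's (mid-thickness) surface.
#'
#' @param reg a [SphericalRegistration-class].
#' @param vertices template vertex indices (default: all).
#' @return length(vertices) x 3 matrix of subject world points (mm).
#' @export
templateVertexToSubjectPoint <- function(reg, vertices = NULL) {
  tv <- normalizeRows(reg@templateSphere@vertices)
  if (!is.null(vertices)) {
    if (any(vertices < 1L | vertices > nrow(tv)))
      stop("template vertex index out of range")
    tv <- tv[vertices, , drop = FALSE]
  }
  loc <- barycentricLocate(subjectSphereMesh(reg), tv)
  applyBarycentric(reg@subjectMesh@vertices, reg@subjectMesh@faces, loc)
}
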