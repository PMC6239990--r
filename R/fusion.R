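#' Build the cohort-averaged volume-to-surface mapping
#'
#' Registration fusion in the volume-to-surface direction: for every
#' template-surface vertex and every subject, the vertex is carried onto
#' the subject's anatomical surface through the spherical registration and
#' then into template-volume space through the subject's inverse volumetric
#' chain; the per-subject template-volume coordinates are averaged
#' arithmetically across the cohort.
#'
#' Subjects whose chain cannot map a vertex (outside the field hull) are
#' excluded for that vertex with a warning; a vertex with no contributing
#' subject is an error.
#'
#' @param cohort list of [SubjectBundle-class].
#' @param templateSphere the common template sphere [TriangleMesh-class].
#' @return a [VolToSurfMapping-class].
#' @export
# One subject's contribution to the volume-to-surface mapping: every
# template vertex carried onto the subject surface and back into
# template-volume space (NA rows where the inverse chain has no hull).
subjectVertexCoords <- function(bundle) {
  p <- templateVertexToSubjectPoint(bundle@reg)
  mapPoints(bundle@invVolChain, p, outside = "na")
}

buildVol2Surf <- function(cohort, templateSphere) {
  if (length(cohort) < 1L) stop("cohort must contain at least one subject")
  nv <- nrow(templateSphere@vertices)
  acc <- matrix(0, nv, 3)
  cnt <- integer(nv)
  nDropped <- 0L
  for (b in cohort) {
    q <- subjectVertexCoords(b)
    ok <- is.finite(q[, 1])
    nDropped <- nDropped + sum(!ok)
    acc[ok, ] <- acc[ok, ] + q[ok, , drop = FALSE]
    cnt <- cnt + ok
  }
  if (nDropped > 0L)
    warning(nDropped, " vertex/subject pair(s) fell outside a subject's ",
            "field hull and were excluded from the average")
  if (any(cnt == 0L))
    stop(sum(cnt == 0L), " vertex/vertices had no contributing subject")
  new("VolToSurfMapping", coords = acc / cnt,
      nSubjects = length(cohort), nContributing = cnt)
}

#' Build the cohort-averaged surface-to-volume mapping with coverage masks
#'
#' For every subject, each template-grid voxel center is mapped into the
#' subject's anatomical space; voxels landing inside that subject's
#' cortical ribbon are assigned the common-sphere coordinate of the nearest
#' subject mid-surface vertex. Per voxel, the coverage fraction is the
#' share of subjects contributing; sphere coordinates are averaged
#' arithmetically and renormalized to unit length. The tight and loose
#' masks keep voxels whose coverage is at least `tightThresh` /
#' `looseThresh` (inclusive).
#'
#' @param cohort list of [SubjectBundle-class].
#' @param templateGrid list with `dim` and `affine`, or a
#'   [VolumeImage-class] defining the template grid.
#' @param tightThresh,looseThresh coverage thresholds, defaults 0.50 / 0.15.
#' @return an unfinalized [SurfToVolMapping-class] (run [dilateMapping()]
#'   then [finalizeSurf2Vol()] to fill the loose mask and assign vertices).
#' @export
buildSurf2Vol <- function(cohort, templateGrid, tightThresh = 0.5,
                          looseThresh = 0.15) {
  if (length(cohort) < 1L) stop("cohort must contain at least one subject")
  if (!(0 < looseThresh && looseThresh <= tightThresh && tightThresh <= 1))
    stop("need 0 < looseThresh <= tightThresh <= 1")
  if (is(templateGrid, "VolumeImage"))
    templateGrid <- list(dim = dim(templateGrid@data),
                         affine = templateGrid@affine)
  d <- as.integer(templateGrid$dim)
  centers <- gridCenters(d, templateGrid$affine)
  nvox <- nrow(centers)
  acc <- matrix(0, nvox, 3)
  cnt <- integer(nvox)
  for (b in cohort) {
    y <- mapPoints(b@volChain, centers, outside = "na")
    rib <- b@ribbonMask
    vox <- worldToVoxelPoints(y, rib@affine)
    vox[!is.finite(y[, 1]), ] <- NA_real_
    inside <- cppSampleGrid(as.double(rib@data), dim(rib@data), 1L, vox,
                            1L)[, 1]
    hit <- which(is.finite(inside) & inside != 0)
    if (!length(hit)) next
    nn <- cppNearestPoint(b@reg@subjectMesh@vertices,
                          y[hit, , drop = FALSE])
    acc[hit, ] <- acc[hit, ] + b@reg@sphereCoords[nn, , drop = FALSE]
    cnt[hit] <- cnt[hit] + 1L
  }
  if (all(cnt == 0L))
    stop("no voxel was covered by any subject's ribbon; ",
         "cohort and template grid are inconsistent")
  coverage <- cnt / length(cohort)
  mean <- acc / ifelse(cnt > 0L, cnt, NA_real_)
  nrm <- rowNorms(mean)
  sph <- mean / ifelse(is.finite(nrm) & nrm > 0, nrm, NA_real_)
  sph[cnt == 0L, ] <- NA_real_
  tight <- coverage >= tightThresh
  loose <- coverage >= looseThresh
  new("SurfToVolMapping",
      sphereCoords = array(sph, dim = c(d, 3L)),
      coverage = array(coverage, dim = d),
      vertexIndex = array(0L, dim = d),
      tightMask = array(tight, dim = d),
      looseMask = array(loose, dim = d),
      affine = templateGrid$affine,
      tightThresh = tightThresh, looseThresh = looseThresh,
      nSubjects = length(cohort),
      templateSphere = TriangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
      finalized = FALSE)
}

#' Grow the tight-mask mapping into the loose mask
#'
#' Every loose-but-not-tight voxel receives the averaged sphere coordinate
#' of its Euclidean-nearest tight-mask voxel (voxel-center distance in
#' world mm, so anisotropic grids behave correctly); ties resolve to the
#' lowest linear index (first grid axis fastest). Tight-voxel assignments
#' are untouched.
#'
#' @param m a [SurfToVolMapping-class].
#' @return the dilated [SurfToVolMapping-class].
#' @export
dilateMapping <- function(m) {
  if (!any(m@tightMask)) stop("tight mask is empty")
  d <- dim(m@coverage)
  centers <- gridCenters(d, m@affine)
  tightIdx <- which(m@tightMask)        # ascending linear index
  fillIdx <- which(m@looseMask & !m@tightMask)
  if (length(fillIdx)) {
    nn <- cppNearestPoint(centers[tightIdx, , drop = FALSE],
                          centers[fillIdx, , drop = FALSE])
    src <- tightIdx[nn]
    sph <- matrix(m@sphereCoords, ncol = 3L)
    sph[fillIdx, ] <- sph[src, , drop = FALSE]
    m@sphereCoords <- array(sph, dim = c(d, 3L))
    if (m@finalized) m@vertexIndex[fillIdx] <- m@vertexIndex[src]
  }
  m
}

#' Assign final template vertices on the loose mask
#'
#' For every loose-mask voxel carrying an averaged sphere coordinate, the
#' final template vertex is the nearest template-sphere vertex to that
#' (renormalized) coordinate. Voxels whose subject sphere coordinates
#' averaged to zero norm (antipodal cancellation) are flagged, excluded
#' with a warning, and keep vertex index 0.
#'
#' @param m a [SurfToVolMapping-class] (after [dilateMapping()] if the
#'   loose mask is to be fully assigned).
#' @param templateSphere the template sphere [TriangleMesh-class].
#' @return the finalized [SurfToVolMapping-class].
#' @export
finalizeSurf2Vol <- function(m, templateSphere) {
  d <- dim(m@coverage)
  sph <- matrix(m@sphereCoords, ncol = 3L)
  looseIdx <- which(m@looseMask)
  valid <- looseIdx[is.finite(sph[looseIdx, 1])]
  degenerate <- setdiff(looseIdx, valid)
  if (length(degenerate))
    warning(length(degenerate), " loose-mask voxel(s) had no usable ",
            "averaged sphere coordinate and were excluded")
  vi <- array(0L, dim = d)
  if (length(valid)) {
    tv <- normalizeRows(templateSphere@vertices)
    vi[valid] <- cppNearestPoint(tv, sph[valid, , drop = FALSE])
  }
  m@vertexIndex <- vi
  m@templateSphere <- templateSphere
  m@finalized <- TRUE
  m
}

#' Registration-fusion mapping from a cohort subset
#'
#' [buildVol2Surf()] restricted to a subset of the cohort, deterministic
#' given the subject order; used by the convergence-versus-cohort-size
#' experiment.
#'
#' @param cohort list of [SubjectBundle-class].
#' @param subset integer indices into `cohort` (default: all).
#' @param templateSphere the template sphere.
#' @return a [VolToSurfMapping-class].
#' @export
averagePartial <- function(cohort, subset = seq_along(cohort),
                           templateSphere) {
  if (length(subset) < 1L) stop("subset must be non-empty")
  if (any(subset < 1L | subset > length(cohort)))
    stop("subset indices out of range")
  buildVol2Surf(cohort[subset], templateSphere)
}

#' Single-registration baseline
#'
#' The identical pipeline to registration fusion run with a single bundle
#' whose "subject" is the volumetric template itself (the surface-recon-
#' of-the-template approach): N = 1, no averaging benefit.
#'
#' @param templateBundle one [SubjectBundle-class].
#' @param templateSphere the template sphere.
#' @param templateGrid template grid (list with `dim`, `affine`, or a
#'   [VolumeImage-class]).
#' @param tightThresh,looseThresh coverage thresholds.
#' @return list with elements `vol2surf` and `surf2vol` (dilated and
#'   finalized).
#' @export
buildSingleRegistrationBaseline <- function(templateBundle, templateSphere,
                                            templateGrid,
                                            tightThresh = 0.5,
                                            looseThresh = 0.15) {
  cohort <- list(templateBundle)
  v2s <- buildVol2Surf(cohort, templateSphere)
  s2v <- buildSurf2Vol(cohort, templateGrid, tightThresh, looseThresh)
  s2v <- finalizeSurf2Vol(dilateMapping(s2v), templateSphere)
  list(vol2surf = v2s, surf2vol = s2v)
}

#' Affine baseline
#'
#' Builds both mapping directions from a single affine between the template
#' volume and the surface-template volume, concatenated with a supplied
#' vertex-to-volume coordinate table, then masked and dilated with the same
#' machinery as registration fusion (N = 1).
#'
#' @param affine an [AffineTransform-class] mapping template volume ->
#'   surface-template volume (world mm).
#' @param templateSurfaceMap list with `vertexVolumeCoords` (V x 3 world
#'   coordinates of each template-surface vertex in surface-template volume
#'   space), `ribbon` (binary [VolumeImage-class] in that same space) and
#'   `templateSphere` (the template sphere mesh).
#' @param templateGrid template grid (list with `dim`, `affine`, or a
#'   [VolumeImage-class]).
#' @param tightThresh,looseThresh coverage thresholds.
#' @return list with elements `vol2surf` and `surf2vol`.
#' @export
buildAffineBaseline <- function(affine, templateSurfaceMap, templateGrid,
                                tightThresh = 0.5, looseThresh = 0.15) {
  sph <- templateSurfaceMap$templateSphere
  anat <- TriangleMesh(asPoints(templateSurfaceMap$vertexVolumeCoords),
                       sph@faces)
  reg <- SphericalRegistration(anat, sph@vertices, sph)
  inv <- AffineTransform(solve(affine@matrix),
                         source = affine@target, target = affine@source)
  bundle <- SubjectBundle("surface-template-volume",
                          volChain = transformChain(affine),
                          invVolChain = transformChain(inv),
                          reg = reg,
                          ribbonMask = templateSurfaceMap$ribbon)
  buildSingleRegistrationBaseline(bundle, sph, templateGrid,
                                  tightThresh, looseThresh)
}
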