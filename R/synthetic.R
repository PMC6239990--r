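# ---- synthetic shell-phantom world -----------------------------------------
#
# The phantom replaces brain anatomy with a spherical "cortical ribbon"
# shell centered in a cubic grid: every geometric quantity (shell volume,
# coverage, the true volume<->surface correspondence) has a closed form, so
# the fusion, projection and evaluation machinery can be validated against
# analytic ground truth. Realism of anatomy or MRI intensities is a
# non-goal.

templateAffine <- function(spec) {
  a <- diag(c(rep(spec@voxelSize, 3), 1))
  a[1:3, 4] <- -(spec@gridShape - 1) * spec@voxelSize / 2
  a
}

templateGridSpec <- function(template) {
  list(dim = dim(template$ribbon@data), affine = template$ribbon@affine)
}

# Farthest-point sampling of nParcels seed directions among the sphere
# vertices; the first seed is a seeded uniform draw, ties go to the lowest
# vertex index.
parcelSeedDirections <- function(dirs, nParcels, seed) {
  set.seed(seed)
  chosen <- sample.int(nrow(dirs), 1L)
  minDist <- acos(pmin(1, pmax(-1, dirs %*% dirs[chosen, ])))
  for (k in seq_len(nParcels - 1L)) {
    nxt <- which.max(minDist)
    chosen <- c(chosen, nxt)
    minDist <- pmin(minDist,
                    acos(pmin(1, pmax(-1, dirs %*% dirs[nxt, ]))))
  }
  dirs[chosen, , drop = FALSE]
}

# Angular-sector label of each direction: nearest seed direction, ties to
# the lowest label id.
directionLabels <- function(dirs, seedDirs) {
  as.integer(max.col(dirs %*% t(seedDirs), ties.method = "first"))
}

#' Build the phantom template
#'
#' The template world: a binary shell ribbon (`rIn <= |x| <= rOut`, world
#' mm, centered), an icosphere mid-thickness surface at radius
#' `(rIn + rOut) / 2`, the unit template sphere, and an angular
#' parcellation into `nParcels` sectors seeded by farthest-point sampling —
#' identical by construction in the volume (each ribbon voxel labeled by
#' its direction) and on the vertices. The two "hemispheres" are the x < 0
#' and x >= 0 halves.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `ribbon` ([VolumeImage-class], integer 0/1),
#'   `midSurface` and `sphere` ([TriangleMesh-class]), `volParcellation`
#'   and `vertexParcellation` ([Parcellation-class]), `labels`
#'   ([LabelTable-class]), `seedDirections`, and `spec`.
#' @export
makeTemplate <- function(spec) {
  validObject(spec)
  aff <- templateAffine(spec)
  d <- rep(spec@gridShape, 3L)
  centers <- gridCenters(d, aff)
  r <- rowNorms(centers)
  ribbon <- array(as.integer(r >= spec@rIn & r <= spec@rOut), dim = d)

  sphere <- icosphere(spec@subdivisions, radius = 1)
  rMid <- (spec@rIn + spec@rOut) / 2
  midSurface <- TriangleMesh(sphere@vertices * rMid, sphere@faces)

  seedDirs <- parcelSeedDirections(sphere@vertices, spec@nParcels,
                                   drawSeed(spec@seed, 0L, "parcels"))
  tbl <- LabelTable(seq_len(spec@nParcels))

  vol <- array(0L, dim = d)
  rib <- which(ribbon != 0L)
  vol[rib] <- directionLabels(centers[rib, , drop = FALSE] / r[rib], seedDirs)
  volSpace <- list(type = "volume", dim = d, affine = aff)
  vtxSpace <- list(type = "surface", nVertices = nrow(sphere@vertices))

  list(ribbon = VolumeImage(ribbon, aff),
       midSurface = midSurface,
       sphere = sphere,
       volParcellation = Parcellation(vol, tbl, volSpace),
       vertexParcellation = Parcellation(
         directionLabels(sphere@vertices, seedDirs), tbl, vtxSpace),
       labels = tbl,
       seedDirections = seedDirs,
       spec = spec)
}

# ---- per-subject warps ------------------------------------------------------

controlDim <- 6L

controlAffineFor <- function(spec) {
  extent <- (spec@gridShape - 1) * spec@voxelSize
  spacing <- extent / (controlDim - 1)
  a <- diag(c(rep(spacing, 3), 1))
  a[1:3, 4] <- -extent / 2
  a
}

# Truncated-and-renormalized separable Gaussian smoothing of a control-grid
# vector field; sigma in control-node spacings (fixed at 2).
smoothControl <- function(ctrl, sigma = 2) {
  half <- ceiling(3 * sigma)
  kern <- exp(-0.5 * ((-half:half) / sigma)^2)
  n <- dim(ctrl)[1]
  for (axis in 1:3) {
    perm <- switch(axis, c(1, 2, 3, 4), c(2, 1, 3, 4), c(3, 1, 2, 4))
    x <- aperm(ctrl, perm)
    dd <- dim(x)
    m <- matrix(x, nrow = dd[1])
    sm <- matrix(0, nrow = dd[1], ncol = ncol(m))
    wt <- numeric(dd[1])
    for (o in -half:half) {
      w <- kern[o + half + 1]
      src <- seq_len(dd[1]) + o
      ok <- src >= 1 & src <= dd[1]
      sm[ok, ] <- sm[ok, ] + w * m[src[ok], ]
      wt[ok] <- wt[ok] + w
    }
    sm <- sm / wt
    x <- array(sm, dim = dd)
    ctrl <- aperm(x, order(perm))
  }
  ctrl
}

rawControlField <- function(spec, index) {
  set.seed(drawSeed(spec@seed, index, "warp"))
  noise <- array(rnorm(controlDim^3 * 3), dim = c(rep(controlDim, 3L), 3L))
  smoothControl(noise)
}

# Trilinear upsampling of a control field to the full template grid,
# returned as an n_voxels x 3 matrix in linear-index order.
upsampleControl <- function(ctrl, spec) {
  aff <- templateAffine(spec)
  d <- rep(spec@gridShape, 3L)
  centers <- gridCenters(d, aff)
  vox <- worldToVoxelPoints(centers, controlAffineFor(spec))
  vox[] <- pmin(pmax(vox, 0), controlDim - 1)  # clamp boundary round-off
  cppSampleGrid(as.double(ctrl), rep(controlDim, 3L), 3L, vox, 0L)
}

rodrigues <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Jittered spherical registration: a small random rotation (angle up to
# half the jitter budget) plus a smooth tangential displacement field
# (linear in position, projected to the tangent plane, scaled to the other
# half of the budget), then renormalization.
jitteredSphereCoords <- function(spec, index, sphere) {
  p <- sphere@vertices
  if (spec@jitterDeg == 0) return(p)
  set.seed(drawSeed(spec@seed, index, "sphere"))
  budget <- spec@jitterDeg * pi / 180
  axis <- rnorm(3)
  angle <- runif(1, 0, budget / 2)
  R <- rodrigues(axis, angle)
  A <- matrix(rnorm(9), 3, 3)
  t <- p %*% t(A)
  t <- t - p * rowSums(t * p)        # tangential component
  mx <- max(rowNorms(t))
  if (mx > 0) t <- t * (runif(1, 0, budget / 2) / mx)
  normalizeRows((p + t) %*% t(R))
}

# Assemble a SubjectBundle (and its exact generating transforms) from a
# full-grid displacement field.
subjectFromField <- function(spec, index, template, fullField) {
  aff <- templateAffine(spec)
  d <- rep(spec@gridShape, 3L)
  id <- sprintf("sub-%03d", index)
  fwd <- DenseTransform(VectorField(array(fullField, dim = c(d, 3L)), aff),
                        source = "template", target = id)
  inv <- invertField(fwd, tol = 0.005, maxIter = 200L)

  vMid <- template$midSurface@vertices
  subjVerts <- vMid + sampleField(fwd@field, vMid, outside = "zero")
  subjMesh <- TriangleMesh(subjVerts, template$midSurface@faces)

  ribbon <- resampleVolume(template$ribbon, transformChain(inv),
                           target = list(dim = d, affine = aff),
                           interp = "nearest")

  reg <- SphericalRegistration(
    subjMesh, jitteredSphereCoords(spec, index, template$sphere),
    template$sphere)

  bundle <- SubjectBundle(id,
                          volChain = transformChain(fwd),
                          invVolChain = transformChain(inv),
                          reg = reg, ribbonMask = ribbon)
  list(bundle = bundle, forward = fwd, inverse = inv)
}

#' Generate one phantom subject
#'
#' The subject's anatomy is the template warped by a smooth random
#' displacement field: per-node Gaussian noise on a coarse control grid,
#' Gaussian-smoothed (sigma = 2 node spacings), trilinearly upsampled, and
#' scaled so the maximum displacement norm equals `amplitude`. The ribbon
#' mask is the warped template ribbon (nearest-neighbour); the spherical
#' registration is the template sphere under a small random rotation plus
#' smooth tangential jitter. The exact generating field and its fixed-point
#' inverse (tolerance 0.005 mm) are recorded in the returned chains.
#'
#' @param spec a [PhantomSpec-class].
#' @param index subject index (keys all random draws with the master seed).
#' @param template output of [makeTemplate()] (rebuilt when omitted).
#' @return list with `bundle` ([SubjectBundle-class]), `forward` and
#'   `inverse` ([DenseTransform-class]).
#' @export
makeSubject <- function(spec, index = 1L, template = makeTemplate(spec)) {
  full <- upsampleControl(rawControlField(spec, index), spec)
  mx <- max(rowNorms(full))
  if (mx > 0) full <- full * (spec@amplitude / mx)
  subjectFromField(spec, index, template, full)
}

#' Generate a phantom cohort with analytic ground truth
#'
#' Subject draws are keyed by (master seed, subject index, draw name), so a
#' cohort is prefix-stable: the first n subjects of a size-N cohort equal
#' the size-n cohort (required by [averagePartial()] and the convergence
#' experiment). With `recenter = TRUE` (default, N >= 2) the cohort-mean
#' control-node displacement is subtracted from every subject before a
#' common scale factor sets the cohort's maximum displacement to
#' `amplitude`; the template is then the cohort's true center and every
#' subject's maximum displacement is at most `amplitude`.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `template`, `cohort` (list of [SubjectBundle-class]),
#'   `transforms` (per-subject `forward` / `inverse`), and `truth`
#'   (the analytic `vol2surf` / `surf2vol` template mappings).
#' @export
makeCohort <- function(spec) {
  template <- makeTemplate(spec)
  N <- spec@nSubjects
  ctrls <- lapply(seq_len(N), function(i) rawControlField(spec, i))
  if (spec@recenter && N > 1L) {
    m <- Reduce(`+`, ctrls) / N
    ctrls <- lapply(ctrls, function(x) x - m)
  }
  fulls <- lapply(ctrls, upsampleControl, spec = spec)
  mx <- max(vapply(fulls, function(f) max(rowNorms(f)), numeric(1)))
  sc <- if (mx > 0) spec@amplitude / mx else 0
  subjects <- lapply(seq_len(N), function(i)
    subjectFromField(spec, i, template, fulls[[i]] * sc))
  list(template = template,
       cohort = lapply(subjects, `[[`, "bundle"),
       transforms = lapply(subjects, function(su)
         list(forward = su$forward, inverse = su$inverse)),
       truth = groundTruthMappings(template, N))
}

# Analytic template mappings: each surface vertex corresponds to its
# mid-surface world coordinate; each ribbon voxel corresponds to the sphere
# direction of its own position.
groundTruthMappings <- function(template, nSubjects = 1L) {
  sph <- template$sphere
  v2s <- new("VolToSurfMapping", coords = template$midSurface@vertices,
             nSubjects = as.integer(nSubjects),
             nContributing = rep(as.integer(nSubjects),
                                 nrow(sph@vertices)))
  d <- dim(template$ribbon@data)
  centers <- gridCenters(d, template$ribbon@affine)
  rib <- template$ribbon@data != 0L
  sphArr <- matrix(NA_real_, prod(d), 3L)
  idx <- which(rib)
  dirs <- normalizeRows(centers[idx, , drop = FALSE])
  sphArr[idx, ] <- dirs
  vi <- array(0L, dim = d)
  vi[idx] <- cppNearestPoint(sph@vertices, dirs)
  s2v <- new("SurfToVolMapping",
             sphereCoords = array(sphArr, dim = c(d, 3L)),
             coverage = array(as.double(rib), dim = d),
             vertexIndex = vi,
             tightMask = array(rib, dim = d),
             looseMask = array(rib, dim = d),
             affine = template$ribbon@affine,
             tightThresh = 0.5, looseThresh = 0.15,
             nSubjects = as.integer(nSubjects),
             templateSphere = sph, finalized = TRUE)
  list(vol2surf = v2s, surf2vol = s2v)
}

#' Per-subject parcellations in subject space
#'
#' Carries the template parcellation into each subject's space through that
#' subject's true warp (nearest-neighbour), providing the inputs for the
#' projection-evaluation simulations.
#'
#' @param cohortData output of [makeCohort()].
#' @return list of volume [Parcellation-class] objects, one per subject.
#' @export
makeSubjectParcellations <- function(cohortData) {
  template <- cohortData$template
  grid <- templateGridSpec(template)
  volImg <- VolumeImage(array(template$volParcellation@labels,
                              dim = grid$dim), grid$affine)
  lapply(cohortData$cohort, function(b) {
    sub <- resampleVolume(volImg, b@invVolChain, target = grid,
                          interp = "nearest")
    Parcellation(sub@data, template$labels,
                 list(type = "volume", dim = grid$dim, affine = grid$affine))
  })
}

#' Inputs for the affine baseline on the phantom
#'
#' Emulates the real-world situation the affine approach faces: the
#' surface-template volume differs from the volumetric template by a
#' genuinely nonlinear distortion, and only an affine approximation of
#' that relation is available. A seeded smooth warp is decomposed into its
#' least-squares affine part (over the ribbon) and the nonlinear
#' remainder; the remainder is scaled so its maximum norm equals
#' `amplitude` and added back, so `amplitude` controls exactly the
#' irreducible error of the affine approach. The supplied vertex-to-volume
#' table and ribbon live in the distorted space; the supplied affine is
#' the least-squares fit of the final relation.
#'
#' @param spec a [PhantomSpec-class].
#' @param template output of [makeTemplate()].
#' @param amplitude nonlinear-residual amplitude in mm.
#' @return list with `affine` ([AffineTransform-class]) and
#'   `templateSurfaceMap` (see [buildAffineBaseline()]).
#' @export
makeBaselineInputs <- function(spec, template = makeTemplate(spec),
                               amplitude = 3) {
  set.seed(drawSeed(spec@seed, 0L, "baseline-noise"))
  noise <- array(rnorm(controlDim^3 * 3), dim = c(rep(controlDim, 3L), 3L))
  ctrl <- smoothControl(noise, sigma = 1)  # rougher than subject warps
  full <- upsampleControl(ctrl, spec)
  aff <- templateAffine(spec)
  d <- rep(spec@gridShape, 3L)
  centers <- gridCenters(d, aff)
  idx <- which(template$ribbon@data != 0L)

  # split into ribbon-fitted affine part and nonlinear remainder, scaled
  # to the requested residual amplitude
  fit <- lm(full[idx, , drop = FALSE] ~ centers[idx, , drop = FALSE])
  B <- coef(fit)                         # 4 x 3: intercept + slopes
  affPart <- cbind(1, centers) %*% B
  residual <- full - affPart
  mx <- max(rowNorms(residual[idx, , drop = FALSE]))
  if (mx > 0) residual <- residual * (amplitude / mx)
  full <- affPart + residual

  fwd <- DenseTransform(VectorField(array(full, dim = c(d, 3L)), aff),
                        source = "template", target = "surface-template-volume")
  inv <- invertField(fwd, tol = 0.005, maxIter = 200L)

  vMid <- template$midSurface@vertices
  table <- vMid + sampleField(fwd@field, vMid, outside = "zero")
  ribbon <- resampleVolume(template$ribbon, transformChain(inv),
                           target = list(dim = d, affine = aff),
                           interp = "nearest")

  refit <- lm(I(centers[idx, , drop = FALSE] + full[idx, , drop = FALSE]) ~
                centers[idx, , drop = FALSE])
  M <- rbind(cbind(t(coef(refit)[2:4, , drop = FALSE]), coef(refit)[1, ]),
             c(0, 0, 0, 1))
  list(affine = AffineTransform(M, source = "template",
                                target = "surface-template-volume"),
       templateSurfaceMap = list(vertexVolumeCoords = table,
                                 ribbon = ribbon,
                                 templateSphere = template$sphere),
       warp = fwd)
}

#' Write / load a phantom cohort directory
#'
#' Serializes the template, every subject (forward/inverse fields as vector
#' NIfTI referenced from chain manifests, meshes and sphere coordinates as
#' plain-text surfaces, ribbon masks as NIfTI) and the ground-truth tables,
#' plus a JSON manifest.
#'
#' @param cohortData output of [makeCohort()].
#' @param dir output directory (created if needed).
#' @export
writeCohort <- function(cohortData, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  template <- cohortData$template
  spec <- template$spec
  writeVolume(template$ribbon, file.path(dir, "template_ribbon.nii.gz"))
  writeMesh(template$midSurface, file.path(dir, "template_mid.surf.txt"))
  writeMesh(template$sphere, file.path(dir, "template_sphere.surf.txt"))
  writeVolume(VolumeImage(array(template$volParcellation@labels,
                                dim = dim(template$ribbon@data)),
                          template$ribbon@affine),
              file.path(dir, "template_parc.nii.gz"))
  writeVertexData(template$vertexParcellation@labels,
                  file.path(dir, "template_parc.labels.txt"))
  writeLabels(template$labels, file.path(dir, "labels.csv"))
  write.table(template$midSurface@vertices,
              file.path(dir, "truth_vol2surf.tsv"),
              row.names = FALSE, col.names = FALSE)
  ids <- character(0)
  for (i in seq_along(cohortData$cohort)) {
    b <- cohortData$cohort[[i]]
    sd <- file.path(dir, b@id)
    dir.create(sd, showWarnings = FALSE)
    writeChain(b@volChain, file.path(sd, "vol_chain.txt"))
    writeChain(b@invVolChain, file.path(sd, "inv_vol_chain.txt"))
    writeVolume(b@ribbonMask, file.path(sd, "ribbon.nii.gz"))
    writeMesh(b@reg@subjectMesh, file.path(sd, "mid.surf.txt"))
    writeMesh(TriangleMesh(b@reg@sphereCoords, b@reg@subjectMesh@faces),
              file.path(sd, "sphere.surf.txt"))
    ids <- c(ids, b@id)
  }
  manifest <- list(
    generator = "regfuse phantom",
    version = as.character(packageVersion("regfuse")),
    nSubjects = length(ids), subjects = ids,
    gridShape = spec@gridShape, voxelSize = spec@voxelSize,
    rIn = spec@rIn, rOut = spec@rOut, nParcels = spec@nParcels,
    amplitude = spec@amplitude, jitterDeg = spec@jitterDeg,
    seed = spec@seed, subdivisions = spec@subdivisions,
    recenter = spec@recenter)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}

#' @rdname writeCohort
#' @return [readCohort()]: the same structure as [makeCohort()] (the
#'   recorded transforms are read back from the serialized chains).
#' @export
readCohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no cohort manifest found in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  spec <- phantomSpec(gridShape = manifest$gridShape,
                      voxelSize = manifest$voxelSize,
                      rIn = manifest$rIn, rOut = manifest$rOut,
                      nParcels = manifest$nParcels,
                      nSubjects = manifest$nSubjects,
                      amplitude = manifest$amplitude,
                      jitterDeg = manifest$jitterDeg,
                      seed = manifest$seed,
                      subdivisions = manifest$subdivisions,
                      recenter = manifest$recenter)
  ribbon <- readVolume(file.path(dir, "template_ribbon.nii.gz"))
  ribbonData <- ribbon@data
  storage.mode(ribbonData) <- "integer"
  ribbon <- VolumeImage(ribbonData, ribbon@affine)
  mid <- readMesh(file.path(dir, "template_mid.surf.txt"))
  sphere <- readMesh(file.path(dir, "template_sphere.surf.txt"))
  parcVol <- readVolume(file.path(dir, "template_parc.nii.gz"))
  tbl <- readLabels(file.path(dir, "labels.csv"))
  d <- dim(ribbon@data)
  template <- list(
    ribbon = ribbon, midSurface = mid, sphere = sphere,
    volParcellation = Parcellation(as.integer(parcVol@data), tbl,
                                   list(type = "volume", dim = d,
                                        affine = ribbon@affine)),
    vertexParcellation = Parcellation(
      readVertexData(file.path(dir, "template_parc.labels.txt")), tbl,
      list(type = "surface", nVertices = nrow(sphere@vertices))),
    labels = tbl, seedDirections = NULL, spec = spec)
  cohort <- lapply(manifest$subjects, function(id) {
    sd <- file.path(dir, id)
    rib <- readVolume(file.path(sd, "ribbon.nii.gz"))
    ribData <- rib@data
    storage.mode(ribData) <- "integer"
    subjMesh <- readMesh(file.path(sd, "mid.surf.txt"))
    sphMesh <- readMesh(file.path(sd, "sphere.surf.txt"))
    SubjectBundle(id,
                  volChain = readChain(file.path(sd, "vol_chain.txt")),
                  invVolChain = readChain(file.path(sd, "inv_vol_chain.txt")),
                  reg = SphericalRegistration(subjMesh, sphMesh@vertices,
                                              sphere),
                  ribbonMask = VolumeImage(ribData, rib@affine))
  })
  list(template = template, cohort = cohort, transforms = NULL,
       truth = groundTruthMappings(template, length(cohort)))
}
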