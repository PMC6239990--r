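test_that("fusion with identity transforms recovers the template geometry", {
  cd <- tinyIdentityCohort()
  one <- buildVol2Surf(cd$cohort[1], cd$template$sphere)
  expect_equal(one@coords, cd$template$midSurface@vertices,
               tolerance = 1e-9)
  all4 <- buildVol2Surf(cd$cohort, cd$template$sphere)
  expect_lt(max(mappingError(all4, cd$truth$vol2surf)), 0.5)  # voxels (1 mm)
  expect_equal(all4@nSubjects, 4L)
})

test_that("pure opposite translations cancel in the average", {
  cd <- tinyIdentityCohort()
  template <- cd$template
  # same anatomy, volumetric transforms claiming +d and -d: per-subject
  # mappings are shifted by -d and +d, and the fused average is unshifted
  mk <- function(d) {
    tr <- diag(4); tr[1:3, 4] <- d
    inv <- diag(4); inv[1:3, 4] <- -d
    b <- cd$cohort[[1]]
    SubjectBundle(paste0("t", d[1]),
                  volChain = transformChain(AffineTransform(tr)),
                  invVolChain = transformChain(AffineTransform(inv)),
                  reg = b@reg, ribbonMask = b@ribbonMask)
  }
  d <- c(2, 0, 0)
  single <- buildVol2Surf(list(mk(d)), template$sphere)
  expect_equal(single@coords,
               sweep(template$midSurface@vertices, 2, d),
               tolerance = 1e-9)
  m <- buildVol2Surf(list(mk(d), mk(-d)), template$sphere)
  expect_equal(m@coords, template$midSurface@vertices, tolerance = 1e-9)
})

test_that("coverage fractions and masks follow the >= threshold rule", {
  cd <- tinyIdentityCohort()
  template <- cd$template
  grid <- gridOf(template)
  # knock one ribbon voxel out of a single subject's mask -> coverage 0.75
  rib <- which(template$ribbon@data != 0L)
  victim <- rib[17]
  cohort <- cd$cohort
  b1 <- cohort[[1]]
  newMask <- b1@ribbonMask@data
  newMask[victim] <- 0L
  cohort[[1]] <- SubjectBundle(b1@id, b1@volChain, b1@invVolChain, b1@reg,
                               VolumeImage(newMask, b1@ribbonMask@affine))
  m <- buildSurf2Vol(cohort, grid)
  expect_equal(m@coverage[victim], 0.75)
  expect_true(m@tightMask[victim])   # 0.75 >= 0.5
  expect_true(m@looseMask[victim])
  full <- rib[rib != victim]
  expect_true(all(m@coverage[full] == 1))
  expect_true(all(m@coverage[template$ribbon@data == 0L] == 0))

  # all subjects identical: tight = loose = the ribbon footprint
  m2 <- buildSurf2Vol(cd$cohort, grid)
  expect_identical(m2@tightMask, m2@looseMask)
  expect_identical(which(m2@tightMask), rib)

  expect_error(buildSurf2Vol(cd$cohort, grid, tightThresh = 0.5,
                             looseThresh = 0.8), "loose")
})

test_that("threshold arithmetic matches the coverage definition", {
  # coverage (1.0, 0.5, 0.25, 0) with defaults: tight {v1, v2},
  # loose {v1, v2, v3}
  cov <- array(0, dim = c(4, 1, 1))
  cov[, 1, 1] <- c(1, 0.5, 0.25, 0)
  set.seed(20)
  m <- syntheticS2V(cov)
  expect_identical(as.vector(m@tightMask), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(as.vector(m@looseMask), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("dilation equals the exhaustive nearest-tight-voxel search", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    cov <- array(runif(n^3), dim = rep(n, 3))
    aff <- diag(c(1, 1.5, 2, 1))  # anisotropic grid, world-mm distances
    m <- syntheticS2V(cov, affine = aff, tight = 0.8, loose = 0.3)
    if (!any(m@tightMask)) next
    dm <- dilateMapping(m)
    centers <- t(aff %*% rbind(t(as.matrix(expand.grid(
      0:(n - 1), 0:(n - 1), 0:(n - 1)))), 1))[, 1:3]
    tightIdx <- which(m@tightMask)
    sph <- matrix(m@sphereCoords, ncol = 3)
    dsph <- matrix(dm@sphereCoords, ncol = 3)
    for (i in which(m@looseMask & !m@tightMask)) {
      j <- tightIdx[bruteNearest(centers[tightIdx, , drop = FALSE],
                                 centers[i, , drop = FALSE])]
      expect_identical(dsph[i, ], sph[j, ])
    }
    # tight voxels untouched
    expect_identical(dsph[tightIdx, ], sph[tightIdx, ])
  }
})

test_that("dilation ties go to the lowest linear index", {
  cov <- array(0, dim = c(3, 1, 1))
  cov[c(1, 3), 1, 1] <- 1       # two tight voxels equidistant from center
  cov[2, 1, 1] <- 0.3           # loose only
  set.seed(22)
  m <- syntheticS2V(cov, tight = 0.5, loose = 0.2)
  dm <- dilateMapping(m)
  expect_equal(matrix(dm@sphereCoords, ncol = 3)[2, ],
               matrix(m@sphereCoords, ncol = 3)[1, ])
})

test_that("finalization snaps averaged coordinates to template vertices", {
  sphere <- icosphere(2)
  cov <- array(1, dim = c(8, 8, 8))
  set.seed(23)
  m <- syntheticS2V(cov)
  sph <- matrix(m@sphereCoords, ncol = 3)
  sph[1, ] <- sphere@vertices[12, ]       # exactly at vertex 12
  m@sphereCoords <- array(sph, dim = c(8, 8, 8, 3))
  fm <- finalizeSurf2Vol(m, sphere)
  expect_identical(fm@vertexIndex[1], 12L)
  expect_true(fm@finalized)
  idx <- sample(which(fm@looseMask), 500)
  expect_identical(as.vector(fm@vertexIndex[idx]),
                   as.integer(bruteNearest(sphere@vertices, sph[idx, ])))
})

test_that("degenerate zero-norm averages are flagged and excluded", {
  sphere <- icosphere(1)
  cov <- array(1, dim = c(2, 2, 2))
  set.seed(24)
  m <- syntheticS2V(cov)
  sph <- matrix(m@sphereCoords, ncol = 3)
  sph[3, ] <- NA_real_  # antipodal cancellation upstream
  m@sphereCoords <- array(sph, dim = c(2, 2, 2, 3))
  expect_warning(fm <- finalizeSurf2Vol(m, sphere), "excluded")
  expect_identical(fm@vertexIndex[3], 0L)
  expect_true(all(fm@vertexIndex[-3] > 0L))
})

test_that("partial averages are consistent with the full build", {
  cd <- tinyJitterCohort()
  sphere <- cd$template$sphere
  full <- buildVol2Surf(cd$cohort, sphere)
  expect_equal(averagePartial(cd$cohort, seq_along(cd$cohort), sphere)@coords,
               full@coords, tolerance = 0)
  one <- averagePartial(cd$cohort, 3L, sphere)
  expect_equal(one@coords, buildVol2Surf(cd$cohort[3], sphere)@coords,
               tolerance = 0)
  expect_error(averagePartial(cd$cohort, integer(0), sphere), "non-empty")

  # streaming mean over a permuted order equals the batch mean
  set.seed(25)
  perm <- sample(seq_along(cd$cohort))
  per <- lapply(perm, function(i)
    buildVol2Surf(cd$cohort[i], sphere)@coords)
  streaming <- matrix(0, nrow(per[[1]]), 3)
  for (k in seq_along(per))
    streaming <- streaming + (per[[k]] - streaming) / k
  expect_equal(streaming, full@coords, tolerance = 1e-10)
})

test_that("single-registration baseline is the N = 1 pipeline", {
  cd <- tinyIdentityCohort()
  template <- cd$template
  grid <- gridOf(template)
  res <- buildSingleRegistrationBaseline(cd$cohort[[1]], template$sphere,
                                         grid)
  expect_equal(res$vol2surf@coords,
               buildVol2Surf(cd$cohort[1], template$sphere)@coords,
               tolerance = 0)
  rib <- which(cd$cohort[[1]]@ribbonMask@data != 0L)
  expect_identical(which(res$surf2vol@tightMask), rib)
  expect_identical(which(res$surf2vol@looseMask), rib)
})

test_that("affine baseline pushes the supplied table through the affine", {
  cd <- tinyIdentityCohort()
  template <- cd$template
  grid <- gridOf(template)
  tmap <- list(vertexVolumeCoords = template$midSurface@vertices,
               ribbon = template$ribbon,
               templateSphere = template$sphere)
  res <- buildAffineBaseline(AffineTransform(diag(4)), tmap, grid)
  expect_equal(res$vol2surf@coords, template$midSurface@vertices,
               tolerance = 1e-9)

  # translation affine: table lives in the translated space; the mapped
  # template-volume coordinates shift back by exactly that translation
  d <- c(1.5, -2, 0.5)
  tr <- diag(4); tr[1:3, 4] <- d
  tmap2 <- list(vertexVolumeCoords = sweep(template$midSurface@vertices,
                                           2, -d),
                ribbon = VolumeImage(template$ribbon@data,
                                     local({a <- template$ribbon@affine
                                            a[1:3, 4] <- a[1:3, 4] + d; a})),
                templateSphere = template$sphere)
  res2 <- buildAffineBaseline(AffineTransform(tr), tmap2, grid)
  expect_equal(res2$vol2surf@coords, template$midSurface@vertices,
               tolerance = 1e-9)
})

test_that("tight mask is nested in the loose mask for any threshold pair", {
  cd <- tinyJitterCohort()
  grid <- gridOf(cd$template)
  set.seed(26)
  for (rep in 1:3) {
    tight <- runif(1, 0.3, 1)
    loose <- runif(1, 0.05, tight)
    m <- buildSurf2Vol(cd$cohort, grid, tight, loose)
    expect_false(any(m@tightMask & !m@looseMask))
  }
})
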