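test_that("volume-to-surface projection is exact on linear fields", {
  cd <- tinyIdentityCohort()
  truth <- cd$truth$vol2surf
  grid <- gridOf(cd$template)
  cst <- VolumeImage(array(3.25, dim = grid$dim), grid$affine)
  expect_equal(as.vector(projectVolToSurf(cst, truth)),
               rep(3.25, nrow(truth@coords)))

  centers <- t(grid$affine %*% rbind(t(as.matrix(expand.grid(
    seq_len(grid$dim[1]) - 1, seq_len(grid$dim[2]) - 1,
    seq_len(grid$dim[3]) - 1))), 1))[, 1:3]
  ramp <- VolumeImage(array(centers[, 1], dim = grid$dim), grid$affine)
  out <- projectVolToSurf(ramp, truth, "trilinear")
  expect_equal(as.vector(out), truth@coords[, 1], tolerance = 1e-12)

  far <- new("VolToSurfMapping",
             coords = truth@coords + 1000, nSubjects = 1L,
             nContributing = rep(1L, nrow(truth@coords)))
  expect_warning(z <- projectVolToSurf(cst, far), "outside")
  expect_true(all(z == 0))
  expect_equal(attr(z, "nOutside"), nrow(truth@coords))

  lab <- VolumeImage(array(1L, dim = grid$dim), grid$affine)
  expect_error(projectVolToSurf(lab, truth, "trilinear"), "nearest")
})

test_that("surface-to-volume projection stays inside the loose mask", {
  cd <- tinyIdentityCohort()
  m <- cd$truth$surf2vol
  nv <- nrow(cd$template$sphere@vertices)
  vol <- projectSurfToVol(rep(2, nv), m, interp = "nearest")
  expect_true(all(vol@data[m@looseMask] == 2))
  expect_true(all(vol@data[!m@looseMask] == 0))

  labs <- cd$template$vertexParcellation@labels
  lvol <- projectSurfToVol(labs, m, interp = "nearest")
  expect_true(is.integer(lvol@data))
  expect_true(all(lvol@data %in% c(0L, unique(labs))))
  expect_true(all(lvol@data[!m@looseMask] == 0L))
  expect_error(projectSurfToVol(labs, m, interp = "barycentric"), "nearest")

  unf <- syntheticS2V(array(1, dim = c(2, 2, 2)))
  expect_error(projectSurfToVol(rep(1, nv), unf), "finalized")
})

test_that("smooth scalar fields survive the surface-volume round trip", {
  cd <- fixture("roundTrip", function()
    makeCohort(phantomSpec(nSubjects = 1L, amplitude = 0, jitterDeg = 0,
                           seed = 31L)))
  f <- cd$template$sphere@vertices[, 3]  # smooth low-order field
  vol <- projectSurfToVol(f, cd$truth$surf2vol, interp = "barycentric")
  back <- projectVolToSurf(vol, cd$truth$vol2surf, "trilinear")
  expect_lt(max(abs(back - f)), 0.05 * diff(range(f)))
})

test_that("probabilistic maps count label fractions", {
  space <- list(type = "surface", nVertices = 6L)
  tbl <- LabelTable(1:3)
  p1 <- Parcellation(c(1L, 1L, 2L, 2L, 3L, 0L), tbl, space)
  p2 <- Parcellation(c(1L, 2L, 2L, 3L, 3L, 0L), tbl, space)

  single <- makeProbMaps(list(p1))
  expect_true(all(single@probs %in% c(0, 1)))
  expect_equal(unname(single@probs[1, "1"]), 1)

  both <- makeProbMaps(list(p1, p2))
  expect_equal(unname(both@probs[2, "1"]), 0.5)
  expect_equal(unname(both@probs[2, "2"]), 0.5)
  expect_equal(unname(both@probs[4, "2"]), 0.5)
  labeled <- c(1, 2, 3, 4, 5)
  expect_equal(unname(rowSums(both@probs)[labeled]), rep(1, 5))
  expect_equal(unname(rowSums(both@probs)[6]), 0)

  p3 <- Parcellation(c(1L, 1L), tbl, list(type = "surface", nVertices = 2L))
  expect_error(makeProbMaps(list(p1, p3)), "space")
})

test_that("winner-takes-all follows the probability and tie rules", {
  space <- list(type = "surface", nVertices = 3L)
  tbl <- LabelTable(c(1L, 2L))
  p <- new("ProbabilisticMap",
           probs = rbind(c(0.7, 0.3), c(0.5, 0.5), c(0, 0)),
           labels = c(1L, 2L), labelTable = tbl, space = space,
           nSubjects = 10L)
  w <- winnerTakesAll(p)
  expect_identical(w@labels, c(1L, 1L, 0L))

  cd <- tinyIdentityCohort()
  parc <- cd$template$vertexParcellation
  expect_identical(winnerTakesAll(makeProbMaps(list(parc)))@labels,
                   parc@labels)
})

test_that("parcellation boundaries come from label-discordant edges", {
  ico <- icosphere(2)
  space <- list(type = "surface", nVertices = nrow(ico@vertices))
  tbl <- LabelTable(1:2)
  uni <- Parcellation(rep(1L, nrow(ico@vertices)), tbl, space)
  expect_false(any(boundaryVertices(uni, ico)))

  hemi <- Parcellation(ifelse(ico@vertices[, 3] >= 0, 1L, 2L), tbl, space)
  b <- boundaryVertices(hemi, ico)
  # neighbour-scan oracle
  nb <- lapply(seq_len(nrow(ico@vertices)), function(i) integer(0))
  for (r in seq_len(nrow(ico@faces))) {
    f <- ico@faces[r, ]
    for (pair in list(c(1, 2), c(2, 3), c(3, 1))) {
      nb[[f[pair[1]]]] <- union(nb[[f[pair[1]]]], f[pair[2]])
      nb[[f[pair[2]]]] <- union(nb[[f[pair[2]]]], f[pair[1]])
    }
  }
  oracle <- vapply(seq_along(nb), function(i)
    any(hemi@labels[nb[[i]]] != hemi@labels[i]), logical(1))
  expect_identical(b, oracle)
  expect_true(any(b))

  renamed <- Parcellation(ifelse(hemi@labels == 1L, 2L, 1L), tbl, space)
  expect_identical(boundaryVertices(renamed, ico), b)

  pm <- makeProbMaps(list(hemi))
  tb <- thresholdBoundaries(pm, ico)
  expect_identical(tb@labels, hemi@labels)
  expect_identical(attr(tb, "boundary"), b)
})
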