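test_that("affine application is exact", {
  id <- AffineTransform(diag(4))
  expect_equal(applyAffine(id, c(1, 2, 3)), matrix(c(1, 2, 3), 1))
  tr <- diag(4); tr[1, 4] <- 1
  expect_equal(applyAffine(AffineTransform(tr), c(0, 0, 0)),
               matrix(c(1, 0, 0), 1))
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(0, 1, -1, 0), 2)  # 90 degrees about z
  expect_equal(applyAffine(AffineTransform(rot), c(1, 0, 0)),
               matrix(c(0, 1, 0), 1), tolerance = 1e-12)
})

test_that("field sampling is trilinear with a configurable hull policy", {
  aff <- diag(4)
  cst <- VectorField(array(rep(c(2, 0, 0), each = 8), dim = c(2, 2, 2, 3)),
                     aff)
  set.seed(4)
  pts <- matrix(runif(30), 10, 3)
  expect_equal(sampleField(cst, pts),
               matrix(rep(c(2, 0, 0), each = 10), 10, 3))

  # field linear in x: u = (x, 0, 0) at nodes x in {0, 1}
  lin <- array(0, dim = c(2, 2, 2, 3))
  lin[2, , , 1] <- 1
  linf <- VectorField(lin, aff)
  expect_equal(sampleField(linf, c(0.5, 0.5, 0.5)),
               matrix(c(0.5, 0, 0), 1))
  expect_equal(sampleField(linf, c(0.25, 0, 1)), matrix(c(0.25, 0, 0), 1))

  expect_error(sampleField(cst, c(5, 0, 0)), "outside")
  expect_warning(u <- sampleField(cst, c(5, 0, 0), outside = "zero"),
                 "outside")
  expect_equal(u, matrix(0, 1, 3))
})

test_that("chain mapping composes sequentially and matches manual application", {
  expect_equal(mapPoints(transformChain(), c(3, -1, 2)),
               matrix(c(3, -1, 2), 1))

  t1 <- diag(4); t1[1, 4] <- 1
  t2 <- diag(4); t2[2, 4] <- 2
  ch <- transformChain(AffineTransform(t1), AffineTransform(t2))
  set.seed(5)
  pts <- matrix(rnorm(60), 20, 3)
  expect_equal(mapPoints(ch, pts), sweep(pts, 2, c(-1, -2, 0)))

  aff <- diag(c(2, 2, 2, 1))
  set.seed(6)
  fld <- DenseTransform(
    VectorField(array(rnorm(6^3 * 3, sd = 0.3), dim = c(6, 6, 6, 3)), aff),
    "A", "B")
  rot <- diag(4); rot[1:2, 1:2] <- matrix(c(0, 1, -1, 0), 2)
  step2 <- AffineTransform(rot)
  chain <- transformChain(fld, step2)
  pts <- matrix(runif(300, 2, 8), 100, 3)
  manual <- applyAffine(step2, pts + sampleField(fld@field, pts))
  expect_equal(mapPoints(chain, pts), manual, tolerance = 0)
})

test_that("field inversion handles trivial and smooth fields", {
  aff <- diag(4)
  zero <- DenseTransform(VectorField(array(0, dim = c(4, 4, 4, 3)), aff),
                         "A", "B")
  inv <- invertField(zero)
  expect_true(all(inv@field@vectors == 0))
  expect_identical(inv@source, "B")

  cst <- DenseTransform(
    VectorField(array(rep(c(0.5, -0.25, 0), each = 64),
                      dim = c(4, 4, 4, 3)), aff), "A", "B")
  expect_equal(invertField(cst)@field@vectors, -cst@field@vectors,
               tolerance = 0)

  # smooth sinusoidal field, amplitude 1 voxel, one period across the grid
  n <- 32L
  g <- seq_len(n) - 1
  ux <- outer(outer(sin(2 * pi * g / n), cos(2 * pi * g / n)),
              rep(1, n)) * 1
  fld <- array(0, dim = c(n, n, n, 3))
  fld[, , , 1] <- ux
  fwd <- DenseTransform(VectorField(fld, aff), "A", "B")
  inv <- invertField(fwd, tol = 1e-3, maxIter = 200L)
  pts <- gridCenters(rep(n, 3), aff)
  interior <- rowSums(pts > 2 & pts < n - 3) == 3
  round <- mapPoints(transformChain(fwd, inv), pts[interior, ],
                     outside = "zero")
  expect_lt(max(abs(round - pts[interior, ])), 1e-2)

  # inverse of inverse recovers the original within 2 * tol
  inv2 <- invertField(inv, tol = 1e-3, maxIter = 200L)
  nodeErr <- abs(inv2@field@vectors - fwd@field@vectors)
  idx <- array(FALSE, dim = dim(nodeErr))
  idx[3:(n - 3), 3:(n - 3), 3:(n - 3), ] <- TRUE
  expect_lt(max(nodeErr[idx]), 2e-3 + 1e-2)
})

test_that("non-convergent inversion errors with its residual", {
  aff <- diag(4)
  set.seed(8)
  wild <- DenseTransform(
    VectorField(array(rnorm(5^3 * 3, sd = 4), dim = c(5, 5, 5, 3)), aff),
    "A", "B")
  expect_error(invertField(wild, tol = 1e-6, maxIter = 3L),
               "did not converge")
})

test_that("volume resampling follows the pull-back convention", {
  aff <- diag(4)
  ramp <- array(as.double(rep(0:3, 16)), dim = c(4, 4, 4))
  vol <- VolumeImage(ramp, aff)
  expect_equal(resampleVolume(vol, transformChain())@data, ramp)

  # shift the image content by exactly +1 voxel along x: the target-to-
  # source map is a -1 mm translation
  tr <- diag(4); tr[1, 4] <- -1
  shifted <- resampleVolume(vol, transformChain(AffineTransform(tr)))
  expected <- array(0, dim = c(4, 4, 4))
  expected[2:4, , ] <- ramp[1:3, , ]
  expect_equal(shifted@data, expected)

  lab <- array(sample.int(4L, 64, replace = TRUE), dim = c(4, 4, 4))
  lvol <- VolumeImage(lab, aff)
  expect_error(resampleVolume(lvol, transformChain(), interp = "trilinear"),
               "nearest")
  set.seed(9)
  warp <- DenseTransform(
    VectorField(array(rnorm(4^3 * 3, sd = 0.4), dim = c(4, 4, 4, 3)), aff),
    "A", "B")
  out <- resampleVolume(lvol, transformChain(warp), interp = "nearest")
  expect_true(all(out@data %in% c(0L, unique(as.vector(lab)))))
  expect_true(is.integer(out@data))
})

test_that("baking a chain reproduces point mapping on its grid", {
  aff <- diag(4)
  tr <- diag(4); tr[1:3, 4] <- c(0.5, -0.25, 1)
  ch <- transformChain(AffineTransform(tr))
  baked <- bakeChain(ch, list(dim = c(4L, 4L, 4L), affine = aff),
                     source = "A", target = "B")
  pts <- gridCenters(c(4L, 4L, 4L), aff)
  expect_equal(mapPoints(transformChain(baked), pts), mapPoints(ch, pts),
               tolerance = 1e-12)
})
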