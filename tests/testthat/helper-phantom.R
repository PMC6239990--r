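# Shared fixtures: a small phantom world, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 32 mm grid, 9-12 mm shell, level-2 icosphere (162 vertices), 8 parcels.
tinySpec <- function(...) {
  phantomSpec(gridShape = 32L, rIn = 9, rOut = 12, nParcels = 8L,
              subdivisions = 2L, ...)
}

tinyIdentityCohort <- function() {
  fixture("tinyIdentity", function()
    makeCohort(tinySpec(nSubjects = 4L, amplitude = 0, jitterDeg = 0,
                        seed = 11L)))
}

tinyJitterCohort <- function() {
  fixture("tinyJitter", function()
    makeCohort(tinySpec(nSubjects = 8L, amplitude = 1, jitterDeg = 2,
                        seed = 7L)))
}

gridOf <- function(template) {
  list(dim = dim(template$ribbon@data), affine = template$ribbon@affine)
}

# Brute-force nearest-reference-point oracle (first minimum wins).
bruteNearest <- function(ref, query) {
  apply(query, 1, function(q) {
    d2 <- (ref[, 1] - q[1])^2 + (ref[, 2] - q[2])^2 + (ref[, 3] - q[3])^2
    which.min(d2)
  })
}

# Minimal SurfToVolMapping for geometry tests: random unit sphere
# coordinates on the covered voxels of the given coverage array.
syntheticS2V <- function(coverage, affine = diag(4), tight = 0.5,
                        loose = 0.15) {
  d <- dim(coverage)
  sph <- matrix(NA_real_, prod(d), 3)
  idx <- which(coverage > 0)
  raw <- matrix(rnorm(3 * length(idx)), ncol = 3)
  sph[idx, ] <- raw / sqrt(rowSums(raw^2))
  new("SurfToVolMapping", sphereCoords = array(sph, dim = c(d, 3L)),
      coverage = array(coverage, dim = d),
      vertexIndex = array(0L, dim = d),
      tightMask = array(coverage >= tight, dim = d),
      looseMask = array(coverage >= loose, dim = d),
      affine = affine, tightThresh = tight, looseThresh = loose,
      nSubjects = 1L,
      templateSphere = TriangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
      finalized = FALSE)
}
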