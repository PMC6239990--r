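#' @useDynLib regfuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif t.test p.adjust sd lm coef
#' @importFrom utils read.csv write.csv write.table read.table combn
#'   packageVersion
NULL

# Coerce a points argument to an n x 3 double matrix.
asPoints <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L)
      stop("points must be a 3-vector or an n x 3 matrix")
    points <- matrix(as.double(points), 1L, 3L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns")
  storage.mode(points) <- "double"
  points
}

# World coordinates (mm) of continuous 0-based voxel indices, and back.
voxelToWorldPoints <- function(vox, affine) {
  vox <- asPoints(vox)
  t(affine %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
}

worldToVoxelPoints <- function(world, affine) {
  world <- asPoints(world)
  t(solve(affine) %*% rbind(t(world), 1))[, 1:3, drop = FALSE]
}

# World-space centers of every voxel of a grid, in linear-index order
# (first axis fastest), as an n x 3 matrix.
gridCenters <- function(dim3, affine) {
  g <- expand.grid(x = seq_len(dim3[1]) - 1, y = seq_len(dim3[2]) - 1,
                   z = seq_len(dim3[3]) - 1)
  voxelToWorldPoints(as.matrix(g), affine)
}

rowNorms <- function(m) sqrt(rowSums(m^2))

normalizeRows <- function(m) {
  n <- rowNorms(m)
  m / n
}

# Deterministic sub-seed for a named draw: every stochastic draw in the
# synthetic module is keyed by (master seed, subject index, draw name) so
# partial cohorts are prefix-stable.
drawSeed <- function(master, index, name) {
  h <- 7
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147480009
  as.integer((as.double(master %% 2147480009) * 48271 +
                index * 16807 + h) %% 2147480009)
}

is4x4 <- function(m) is.matrix(m) && all(dim(m) == c(4L, 4L)) &&
  all(is.finite(m))

isInvertible <- function(m) {
  ok <- TRUE
  tryCatch(solve(m), error = function(e) ok <<- FALSE)
  ok
}

# Whether data are label-like (stored as integers).
isLabelData <- function(x) is.integer(x)
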