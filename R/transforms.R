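#' Apply an affine transform to world points
#'
#' @param t an [AffineTransform-class].
#' @param points n x 3 matrix (or 3-vector) of world points (mm).
#' @return n x 3 matrix of transformed world points; exact matrix product.
#' @export
applyAffine <- function(t, points) {
  points <- asPoints(points)
  if (!all(is.finite(points))) stop("points must be finite")
  t(t@matrix %*% rbind(t(points), 1))[, 1:3, drop = FALSE]
}

#' Sample a displacement field at world points
#'
#' Component-wise trilinear interpolation of the 8 surrounding grid nodes.
#' Points outside the field's grid hull follow `outside`: `"error"`
#' (default), `"zero"` (zero displacement, with a warning), or `"na"`
#' (NA rows, silent; used by callers that exclude unmappable points).
#'
#' @param f a [VectorField-class].
#' @param points n x 3 matrix of world points (mm).
#' @param outside out-of-hull policy.
#' @return n x 3 matrix of world-mm displacement vectors.
#' @export
sampleField <- function(f, points, outside = c("error", "zero", "na")) {
  outside <- match.arg(outside)
  points <- asPoints(points)
  vox <- worldToVoxelPoints(points, f@affine)
  d <- dim(f@vectors)
  u <- cppSampleGrid(as.double(f@vectors), d[1:3], 3L, vox, 0L)
  bad <- !is.finite(u[, 1])
  if (any(bad)) {
    if (outside == "error")
      stop(sum(bad), " point(s) outside the field grid hull")
    if (outside == "zero") {
      u[bad, ] <- 0
      warning(sum(bad), " point(s) outside the field grid hull; ",
              "zero displacement used")
    }
  }
  u
}

#' Map world points through a transform chain
#'
#' Steps are applied sequentially; dense steps map `x -> x + u(x)` with `u`
#' sampled trilinearly. An empty chain is the identity.
#'
#' @param chain a [TransformChain-class] (or a single transform).
#' @param points n x 3 matrix of world points (mm).
#' @param outside out-of-hull policy for dense steps (see [sampleField()]);
#'   with `"na"`, a point lost at any step stays NA through the rest.
#' @return n x 3 matrix of mapped points.
#' @export
mapPoints <- function(chain, points, outside = c("error", "zero", "na")) {
  outside <- match.arg(outside)
  if (is(chain, "AffineTransform") || is(chain, "DenseTransform"))
    chain <- transformChain(chain)
  p <- asPoints(points)
  for (s in chain@steps) {
    if (is(s, "AffineTransform")) {
      ok <- is.finite(p[, 1])
      p[ok, ] <- applyAffine(s, p[ok, , drop = FALSE])
    } else {
      ok <- is.finite(p[, 1])
      if (any(ok)) {
        u <- sampleField(s@field, p[ok, , drop = FALSE], outside = outside)
        p[ok, ] <- p[ok, , drop = FALSE] + u
      }
    }
  }
  p
}

#' Invert a dense transform by fixed-point iteration
#'
#' Solves for `v` with `(x + v(x)) + u(x + v(x)) = x` on the field's own
#' grid: `v_{k+1}(x) = -u(x + v_k(x))` starting from `v_0 = -u(x)`,
#' stopping when the largest node update falls below `tol` (mm) or after
#' `maxIter` sweeps. Suitable for smooth, moderate-amplitude (invertible)
#' fields. The achieved residual is attached as attribute `"residual"`.
#'
#' @param t a [DenseTransform-class].
#' @param tol convergence tolerance in mm (largest node update).
#' @param maxIter maximum number of sweeps.
#' @return a [DenseTransform-class] mapping target -> source.
#' @export
invertField <- function(t, tol = 0.01, maxIter = 50L) {
  f <- t@field
  d <- dim(f@vectors)
  X <- gridCenters(d[1:3], f@affine)
  u <- matrix(f@vectors, ncol = 3L)  # node displacements, linear-index order
  v <- -u
  res <- Inf
  hi <- d[1:3] - 1
  for (k in seq_len(maxIter)) {
    vox <- worldToVoxelPoints(X + v, f@affine)
    # clamp to the hull: querying the nearest boundary node keeps the
    # iteration contractive where the warp pushes points past the grid edge
    for (j in 1:3) vox[, j] <- pmin(pmax(vox[, j], 0), hi[j])
    vNew <- -cppSampleGrid(as.double(f@vectors), d[1:3], 3L, vox, 0L)
    res <- max(abs(vNew - v))
    v <- vNew
    if (res < tol) break
  }
  if (res >= tol)
    stop(sprintf("field inversion did not converge: residual %.4g mm after %d iterations",
                 res, maxIter))
  inv <- DenseTransform(VectorField(array(v, dim = d), f@affine),
                        source = t@target, target = t@source)
  attr(inv, "residual") <- res
  inv
}

#' Resample a volume through a transform chain (pull-back)
#'
#' The chain must map target-space points to source-space points: each
#' target voxel center is pushed through the chain and the source volume is
#' sampled there. Out-of-hull targets get the fill value 0. Integer (label)
#' data require nearest-neighbour interpolation, which never invents labels.
#'
#' @param vol source [VolumeImage-class].
#' @param chain [TransformChain-class] mapping target space -> source space.
#' @param target target grid: a [VolumeImage-class] to copy the grid from,
#'   or a list with `dim` (3 integers) and `affine` (4 x 4).
#' @param interp `"trilinear"` or `"nearest"`.
#' @return a [VolumeImage-class] on the target grid.
#' @export
resampleVolume <- function(vol, chain, target = vol,
                           interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  if (is.integer(vol@data) && interp != "nearest")
    stop("integer (label) volumes require interp = \"nearest\"")
  if (is(target, "VolumeImage"))
    target <- list(dim = dim(target@data), affine = target@affine)
  src <- mapPoints(chain, gridCenters(target$dim, target$affine),
                   outside = "na")
  vox <- worldToVoxelPoints(src, vol@affine)
  vox[!is.finite(src[, 1]), ] <- NA_real_
  mode <- if (interp == "nearest") 1L else 0L
  vals <- cppSampleGrid(as.double(vol@data), dim(vol@data), 1L, vox, mode)[, 1]
  vals[!is.finite(vals)] <- 0
  out <- array(vals, dim = target$dim)
  if (is.integer(vol@data)) storage.mode(out) <- "integer"
  VolumeImage(out, target$affine)
}

#' Bake a transform chain into a single dense field
#'
#' Evaluates the chain at every node of a stated grid and stores the net
#' displacement, for export or faster repeated application. Trilinear
#' sampling is used for the dense steps, so baking is exact only up to
#' interpolation of the constituent fields.
#'
#' @param chain a [TransformChain-class].
#' @param grid list with `dim` and `affine`, or a [VolumeImage-class].
#' @param source,target space names for the resulting transform.
#' @param outside out-of-hull policy (see [sampleField()]).
#' @return a [DenseTransform-class].
#' @export
bakeChain <- function(chain, grid, source = "source", target = "target",
                      outside = "zero") {
  if (is(grid, "VolumeImage")) grid <- list(dim = dim(grid@data),
                                            affine = grid@affine)
  X <- gridCenters(grid$dim, grid$affine)
  Y <- suppressWarnings(mapPoints(chain, X, outside = outside))
  u <- Y - X
  u[!is.finite(u)] <- 0
  DenseTransform(VectorField(array(u, dim = c(grid$dim, 3L)), grid$affine),
                 source = source, target = target)
}
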