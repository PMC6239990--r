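#' Icosphere mesh
#'
#' Recursively subdivided icosahedron projected to the sphere; level k has
#' `10 * 4^k + 2` vertices. Construction is fully deterministic: vertex
#' order follows discovery order of subdivision midpoints.
#'
#' @param level subdivision level (0 = icosahedron).
#' @param radius sphere radius (mm); the common template sphere uses 1.
#' @return a [TriangleMesh-class], closed and consistently oriented.
#' @export
icosphere <- function(level = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / rowNorms(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    cache <- new.env(hash = TRUE)
    nf <- nrow(f)
    extra <- matrix(0, 2 * nrow(v) + 3 * nf, 3)  # generous midpoint buffer
    nExtra <- 0L
    nBase <- nrow(v)
    midpoint <- function(a, b) {
      key <- if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      # midpoint arguments are always previous-level vertices (<= nBase)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      nExtra <<- nExtra + 1L
      extra[nExtra, ] <<- m
      cache[[key]] <- nBase + nExtra
      nBase + nExtra
    }
    newf <- matrix(0L, nf * 4L, 3L)
    for (j in seq_len(nf)) {
      a <- f[j, 1]; b <- f[j, 2]; cc <- f[j, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(j - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, extra[seq_len(nExtra), , drop = FALSE])
    f <- newf
  }
  TriangleMesh(v * radius, f)
}

# Vertex adjacency (list of neighbour index vectors) from the face matrix.
vertexNeighbors <- function(mesh) {
  f <- mesh@faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
                 f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)])
  adj <- split(edges[, 2], edges[, 1])
  out <- vector("list", nrow(mesh@vertices))
  idx <- as.integer(names(adj))
  for (i in seq_along(adj)) out[[idx[i]]] <- sort(unique(adj[[i]]))
  out
}

# Faces incident to each vertex, padded to a matrix (NA = none).
vertexFaceIncidence <- function(mesh) {
  f <- mesh@faces
  fid <- rep(seq_len(nrow(f)), 3L)
  vid <- as.vector(f)
  byV <- split(fid, vid)
  deg <- max(lengths(byV))
  out <- matrix(NA_integer_, nrow(mesh@vertices), deg)
  idx <- as.integer(names(byV))
  for (i in seq_along(byV)) out[idx[i], seq_along(byV[[i]])] <- byV[[i]]
  out
}
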