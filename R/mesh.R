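## mesh_core: tetrahedral mesh representation, generation, geometry.

#' Construct a TetMesh from vertices and tets
#'
#' Face-neighbour connectivity is rebuilt from scratch and tets are
#' re-oriented to positive signed volume. The mesh must be conforming: each
#' face is shared by at most two tets.
#'
#' @param vertices numeric matrix (n x 3), coordinates in um.
#' @param tets integer matrix (m x 4), 1-based vertex indices.
#' @return a \linkS4class{TetMesh}.
#' @export
tetMesh <- function(vertices, tets) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(tets) != 4L) stop("tets must have 4 columns")
  if (any(is.na(tets)) || any(tets < 1L) || any(tets > nrow(vertices)))
    stop("tet vertex indices out of range")
  tets <- orientTets(vertices, tets)
  nb <- buildNeighbors(tets)
  mesh <- new("TetMesh", vertices = vertices, tets = tets, neighbors = nb)
  validateMesh(mesh)
  mesh
}

## Signed volume (x6) of each tet row.
signedVol6 <- function(vertices, tets) {
  a <- vertices[tets[, 1L], , drop = FALSE]
  b <- vertices[tets[, 2L], , drop = FALSE] - a
  c <- vertices[tets[, 3L], , drop = FALSE] - a
  d <- vertices[tets[, 4L], , drop = FALSE] - a
  b[, 1L] * (c[, 2L] * d[, 3L] - c[, 3L] * d[, 2L]) -
    b[, 2L] * (c[, 1L] * d[, 3L] - c[, 3L] * d[, 1L]) +
    b[, 3L] * (c[, 1L] * d[, 2L] - c[, 2L] * d[, 1L])
}

## Swap two vertices of inverted tets so all signed volumes are positive.
orientTets <- function(vertices, tets) {
  s6 <- signedVol6(vertices, tets)
  flip <- which(s6 < 0)
  if (length(flip)) {
    tmp <- tets[flip, 3L]
    tets[flip, 3L] <- tets[flip, 4L]
    tets[flip, 4L] <- tmp
  }
  tets
}

## Neighbor table: nb[i, f] is the tet sharing the face opposite local
## vertex f of tet i, or NO_NEIGHBOR on the boundary. Faces are matched by
## sorted vertex triple; a face shared by >2 tets is a conformity error.
buildNeighbors <- function(tets) {
  m <- nrow(tets)
  ## face f of tet i = the three vertices excluding local vertex f
  omit <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  faces <- matrix(0L, m * 4L, 3L)
  for (f in 1:4) {
    tri <- tets[, omit[f, ], drop = FALSE]
    ## sort each row of 3
    lo <- pmin(tri[, 1L], tri[, 2L], tri[, 3L])
    hi <- pmax(tri[, 1L], tri[, 2L], tri[, 3L])
    mid <- tri[, 1L] + tri[, 2L] + tri[, 3L] - lo - hi
    faces[seq_len(m) + (f - 1L) * m, ] <- cbind(lo, mid, hi)
  }
  key <- paste(faces[, 1L], faces[, 2L], faces[, 3L])
  tab <- table(key)
  if (any(tab > 2L))
    stop("mesh-integrity error: a face is shared by more than 2 tets")
  grp <- match(key, names(tab))
  ord <- order(grp)
  nb <- matrix(NO_NEIGHBOR, m, 4L)
  tetOf <- rep(seq_len(m), 4L)
  faceOf <- rep(1:4, each = m)
  ## paired faces are adjacent after ordering by group
  cnt <- as.integer(tab)[grp[ord]]
  pos <- ord[cnt == 2L]
  if (length(pos)) {
    first <- pos[seq(1L, length(pos), by = 2L)]
    second <- pos[seq(2L, length(pos), by = 2L)]
    nb[cbind(tetOf[first], faceOf[first])] <- tetOf[second]
    nb[cbind(tetOf[second], faceOf[second])] <- tetOf[first]
  }
  nb
}

#' Validate mesh invariants
#'
#' Checks positive volumes, symmetric neighbour relation and that every
#' interior face is shared by exactly two tets.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @return invisibly TRUE; stops on violation.
#' @export
validateMesh <- function(mesh) {
  s6 <- signedVol6(mesh@vertices, mesh@tets)
  if (any(s6 <= 0))
    stop("mesh-quality error: non-positive tet volume at tet ",
         which(s6 <= 0)[1L])
  nb <- mesh@neighbors
  for (i in seq_len(nrow(nb))) {
    for (f in 1:4) {
      j <- nb[i, f]
      if (j != NO_NEIGHBOR && !any(nb[j, ] == i))
        stop("mesh-integrity error: asymmetric neighbor relation between tets ",
             i, " and ", j)
    }
  }
  invisible(TRUE)
}

#' Number of tets / vertices
#' @param mesh a \linkS4class{TetMesh}.
#' @return integer count.
#' @export
nTets <- function(mesh) nrow(mesh@tets)

#' @rdname nTets
#' @export
nVertices <- function(mesh) nrow(mesh@vertices)

#' Mesh component accessors
#' @param mesh a \linkS4class{TetMesh}.
#' @return the vertex matrix, tet index matrix, or neighbor table.
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @rdname meshVertices
#' @export
meshTets <- function(mesh) mesh@tets

#' @rdname meshVertices
#' @export
meshNeighbors <- function(mesh) mesh@neighbors

setMethod("show", "TetMesh", function(object) {
  nbnd <- sum(object@neighbors == NO_NEIGHBOR)
  cat("TetMesh:", nTets(object), "tets,", nVertices(object), "vertices,",
      nbnd, "boundary faces\n")
  bb <- apply(object@vertices, 2L, range)
  cat(sprintf("  bounding box [%g, %g] x [%g, %g] x [%g, %g] um\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
})

#' Generate a structured cuboid mesh
#'
#' Subdivides a cuboid of the given extents into a grid of cells, each split
#' into six tetrahedra by the Kuhn subdivision (all six tets share the cell's
#' main diagonal). The Kuhn pattern is translation invariant, so the mesh is
#' conforming across cell faces, and the six tets exactly tile each cell.
#'
#' @param dims numeric length 3, box extents in um (all > 0).
#' @param counts integer length 3, cells per axis (all >= 1).
#' @return a \linkS4class{TetMesh} with \code{6 * prod(counts)} tets.
#' @examples
#' m <- cuboidMesh(c(1, 1, 1), c(1, 1, 1))
#' nTets(m)  # 6
#' @export
cuboidMesh <- function(dims, counts) {
  dims <- as.numeric(dims)
  counts <- as.integer(counts)
  if (length(dims) != 3L || length(counts) != 3L)
    stop("dims and counts must have length 3")
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("invalid argument: all extents must be > 0")
  if (any(is.na(counts)) || any(counts < 1L))
    stop("invalid argument: all cell counts must be >= 1")
  nx <- counts[1L]; ny <- counts[2L]; nz <- counts[3L]
  hx <- dims[1L] / nx; hy <- dims[2L] / ny; hz <- dims[3L] / nz
  ## grid vertices, x fastest
  xs <- (0:nx) * hx; ys <- (0:ny) * hy; zs <- (0:nz) * hz
  vertices <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(vertices) <- NULL
  vid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  ## Kuhn subdivision of the unit cell: for each permutation (p1,p2,p3) of
  ## the axes, the tet (0, e_p1, e_p1+e_p2, e_p1+e_p2+e_p3).
  perms <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  cells <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  ci <- cells$i; cj <- cells$j; ck <- cells$k
  ncell <- nrow(cells)
  tets <- matrix(0L, 6L * ncell, 4L)
  for (p in 1:6) {
    step <- diag(3L)[perms[p, ], , drop = FALSE]
    o1 <- step[1L, ]; o2 <- o1 + step[2L, ]; o3 <- o2 + step[3L, ]
    tets[seq_len(ncell) + (p - 1L) * ncell, ] <- cbind(
      vid(ci, cj, ck),
      vid(ci + o1[1L], cj + o1[2L], ck + o1[3L]),
      vid(ci + o2[1L], cj + o2[2L], ck + o2[3L]),
      vid(ci + o3[1L], cj + o3[2L], ck + o3[3L]))
  }
  tetMesh(vertices, tets)
}

#' Compute per-tet geometry tables
#'
#' Volumes by the signed-tetrahedron determinant (absolute value),
#' barycenters as vertex means, shared-face areas by the cross-product
#' formula, and neighbour distances as Euclidean distances between adjacent
#' tets' barycenters.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param degenerateTol volume (um^3) below which a tet is reported as
#'   degenerate. Default 1e-12, far below any realistic um-scale tet.
#' @return a \linkS4class{MeshGeometry}.
#' @export
meshGeometry <- function(mesh, degenerateTol = 1e-12) {
  v <- mesh@vertices; tt <- mesh@tets; nb <- mesh@neighbors
  m <- nrow(tt)
  vol <- abs(signedVol6(v, tt)) / 6
  bad <- which(vol < degenerateTol)
  if (length(bad))
    stop("mesh-quality error: degenerate tet (volume < ", degenerateTol,
         " um^3) at tet ", bad[1L])
  bary <- (v[tt[, 1L], , drop = FALSE] + v[tt[, 2L], , drop = FALSE] +
           v[tt[, 3L], , drop = FALSE] + v[tt[, 4L], , drop = FALSE]) / 4
  omit <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  areas <- matrix(NA_real_, m, 4L)
  dists <- matrix(NA_real_, m, 4L)
  for (f in 1:4) {
    tri <- tt[, omit[f, ], drop = FALSE]
    e1 <- v[tri[, 2L], , drop = FALSE] - v[tri[, 1L], , drop = FALSE]
    e2 <- v[tri[, 3L], , drop = FALSE] - v[tri[, 1L], , drop = FALSE]
    cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
    cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
    cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
    a <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
    j <- nb[, f]
    has <- j != NO_NEIGHBOR
    areas[has, f] <- a[has]
    d <- bary[j[has], , drop = FALSE] - bary[has, , drop = FALSE]
    dists[has, f] <- sqrt(rowSums(d^2))
  }
  new("MeshGeometry", volumes = vol, barycenters = bary,
      faceAreas = areas, neighborDist = dists)
}

#' Geometry accessors
#' @param geom a \linkS4class{MeshGeometry}.
#' @return per-tet volumes (um^3) or barycenters (um).
#' @export
tetVolumes <- function(geom) geom@volumes

#' @rdname tetVolumes
#' @export
tetBarycenters <- function(geom) geom@barycenters

setMethod("show", "MeshGeometry", function(object) {
  cat("MeshGeometry:", length(object@volumes), "tets, total volume",
      format(sum(object@volumes)), "um^3\n")
})
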