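## partition_parallel: mesh partitioning, Metis interchange, cross-rank
## dependency tables.

#' Construct a partition from a tet -> rank map
#'
#' @param rankOf integer vector, one 0-based rank id per tet.
#' @param nRanks number of ranks; default max(rankOf) + 1.
#' @return a \linkS4class{MeshPartition}.
#' @export
meshPartition <- function(rankOf, nRanks = NULL) {
  rankOf <- as.integer(rankOf)
  if (any(is.na(rankOf)) || any(rankOf < 0L))
    stop("rank ids must be nonnegative integers")
  if (is.null(nRanks)) nRanks <- max(rankOf) + 1L
  if (any(rankOf >= nRanks)) stop("rank id >= nRanks")
  new("MeshPartition", rankOf = rankOf, nRanks = as.integer(nRanks))
}

#' Partition accessors
#' @param partition a \linkS4class{MeshPartition}.
#' @param rank 0-based rank id.
#' @param mesh the partitioned \linkS4class{TetMesh} (where connectivity is
#'   needed).
#' @return see individual functions.
#' @export
partitionRanks <- function(partition) partition@nRanks

#' @rdname partitionRanks
#' @export
rankOfTet <- function(partition) partition@rankOf

#' @rdname partitionRanks
#' @export
hostedTets <- function(partition, rank) which(partition@rankOf == rank)

#' Boundary tets of a rank: hosted tets with at least one face-neighbour
#' hosted by another rank.
#' @rdname partitionRanks
#' @export
boundaryTets <- function(mesh, partition, rank) {
  nb <- mesh@neighbors
  ro <- partition@rankOf
  hosted <- hostedTets(partition, rank)
  hosted[vapply(hosted, function(t) {
    js <- nb[t, nb[t, ] != NO_NEIGHBOR]
    any(ro[js] != rank)
  }, logical(1L))]
}

#' Neighbour ranks: ranks sharing at least one interior face with this rank.
#' @rdname partitionRanks
#' @export
neighborRanks <- function(mesh, partition, rank) {
  nb <- mesh@neighbors
  ro <- partition@rankOf
  hosted <- hostedTets(partition, rank)
  js <- nb[hosted, , drop = FALSE]
  js <- js[js != NO_NEIGHBOR]
  sort(setdiff(unique(ro[js]), rank))
}

setMethod("show", "MeshPartition", function(object) {
  tab <- tabulate(object@rankOf + 1L, object@nRanks)
  cat("MeshPartition:", length(object@rankOf), "tets over", object@nRanks,
      "ranks (", min(tab), "-", max(tab), "tets/rank )\n")
})

#' Linear grid partitioner
#'
#' Bins tets by barycenter into a parts_x x parts_y x parts_z grid over the
#' mesh bounding box; the rank id is the lexicographic bin index (x fastest,
#' z slowest). With parts = (1, 5, p/5) this reproduces the y-z linear
#' partitioning commonly used for elongated cuboid geometries.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param parts integer length 3, partitions per axis.
#' @param geom optional precomputed \linkS4class{MeshGeometry}.
#' @return a \linkS4class{MeshPartition} with \code{prod(parts)} ranks.
#' @export
partitionLinear <- function(mesh, parts, geom = NULL) {
  parts <- as.integer(parts)
  if (length(parts) != 3L || any(parts < 1L))
    stop("parts must be 3 positive counts")
  if (is.null(geom)) geom <- meshGeometry(mesh)
  b <- geom@barycenters
  bin <- function(x, k) {
    lo <- min(x); hi <- max(x)
    if (hi <= lo) return(rep(0L, length(x)))
    i <- floor((x - lo) / (hi - lo) * k)
    as.integer(pmin(i, k - 1L))
  }
  ix <- bin(b[, 1L], parts[1L])
  iy <- bin(b[, 2L], parts[2L])
  iz <- bin(b[, 3L], parts[3L])
  rankOf <- ix + parts[1L] * (iy + parts[2L] * iz)
  nRanks <- prod(parts)
  empty <- setdiff(0:(nRanks - 1L), unique(rankOf))
  if (length(empty))
    warning("empty rank(s): ", paste(empty, collapse = ", "),
            " (legal but wasteful)")
  meshPartition(rankOf, nRanks)
}

#' Read / write Metis-style partition files (.epart)
#'
#' One integer rank id per tet line; rank count inferred as max + 1.
#'
#' @param path file path.
#' @param nTets expected number of tets (validated against the line count).
#' @return a \linkS4class{MeshPartition} (reader) or \code{path} (writer).
#' @export
readPartition <- function(path, nTets = NULL) {
  x <- scan(path, what = integer(), quiet = TRUE)
  if (!is.null(nTets) && length(x) != nTets)
    stop("mismatch error: partition file has ", length(x),
         " lines for ", nTets, " tets")
  meshPartition(x)
}

#' @rdname readPartition
#' @param partition a \linkS4class{MeshPartition}.
#' @export
writePartition <- function(partition, path) {
  writeLines(as.character(partition@rankOf), path)
  invisible(path)
}

#' Export the tet connectivity graph in Metis .graph format
#'
#' First line "nvertices nedges", then one line per tet listing its 1-based
#' face-neighbours — the input format external graph partitioners consume.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param path output path.
#' @return invisibly \code{path}.
#' @export
writeMetisGraph <- function(mesh, path) {
  nb <- mesh@neighbors
  nEdges <- sum(nb != NO_NEIGHBOR) / 2L
  lines <- vapply(seq_len(nrow(nb)), function(t)
    paste(nb[t, nb[t, ] != NO_NEIGHBOR], collapse = " "), character(1L))
  writeLines(c(paste(nrow(nb), nEdges), lines), path)
  invisible(path)
}

#' Build a rank's dependency tables
#'
#' The serial update dependency lists truncated at rank boundaries, plus the
#' species update dependency lists deps(S): for each boundary (tet, diffusive
#' species), the hosted events whose propensity must be refreshed when that
#' species' count in that tet changes via incoming cross-rank diffusion.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param model a \linkS4class{ReactionModel}.
#' @param partition a \linkS4class{MeshPartition}.
#' @param rank 0-based rank id.
#' @return list with \code{depsR} and \code{depsD} (serial deps of hosted
#'   reaction / diffusion events, intersected with hosted events; named by
#'   event id), \code{depsS} (named "tet.species" -> hosted event ids),
#'   \code{hostedEvents}, and the layout.
#' @export
buildRankTables <- function(mesh, model, partition, rank) {
  dep <- buildEventDeps(mesh, model)
  nLoc <- dep$nLoc; nR <- dep$nR; nD <- dep$nD
  hosted <- hostedTets(partition, rank)
  hostedEv <- as.integer(outer(seq_len(nLoc), (hosted - 1L) * nLoc, `+`))
  hostedSet <- logical(length(dep$deps))
  hostedSet[hostedEv] <- TRUE
  pick <- function(tets, locals) {
    ids <- as.integer(outer(locals, (tets - 1L) * nLoc, `+`))
    out <- lapply(ids, function(e) dep$deps[[e]][hostedSet[dep$deps[[e]]]])
    names(out) <- ids
    out
  }
  depsR <- if (nR) pick(hosted, seq_len(nR)) else list()
  depsD <- if (nD) pick(hosted, nR + seq_len(nD)) else list()
  ## deps(S): only boundary tets can receive cross-rank diffusion
  btets <- boundaryTets(mesh, partition, rank)
  depsS <- list()
  spNames <- model@species$name
  rxns <- model@reactions
  for (t in btets) {
    base <- (t - 1L) * nLoc
    for (j in seq_len(nD)) {
      s <- dep$diffIdx[j]
      rs <- which(vapply(rxns, function(r) spNames[s] %in% names(r$lhs),
                         logical(1L)))
      ids <- base + c(rs, nR + j)
      depsS[[paste0(t, ".", spNames[s])]] <- ids
    }
  }
  list(depsR = depsR, depsD = depsD, depsS = depsS,
       hostedEvents = hostedEv, nR = nR, nD = nD, nLoc = nLoc,
       diffNames = dep$diffNames)
}
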