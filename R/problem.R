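## Assembly of a runnable simulation problem: precomputes the flattened
## tables (scaled rate constants per tet, diffusion geometry, dependency
## lists) consumed by the C++ cores.

#' Assemble a simulation problem
#'
#' @param model a \linkS4class{ReactionModel}.
#' @param mesh a \linkS4class{TetMesh}.
#' @param init initial molecule counts: either an integer matrix
#'   (tets x species), or a named vector of whole-mesh totals to be placed
#'   uniformly (see \code{\link{uniformInit}}), or NULL to use the model's
#'   attached totals.
#' @return an \linkS4class{SSAProblem}.
#' @export
ssaProblem <- function(model, mesh, init = NULL) {
  geom <- meshGeometry(mesh)
  rates <- diffusionRates(mesh, geom, model)
  nT <- nTets(mesh)
  spNames <- model@species$name
  S <- length(spNames)
  if (is.null(init)) init <- initialTotals(model)
  if (is.matrix(init)) {
    counts <- init
    if (nrow(counts) != nT || ncol(counts) != S)
      stop("init matrix must be nTets x nSpecies")
  } else {
    counts <- uniformInit(mesh, init, geom = geom, species = spNames)
  }
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("initial counts must be nonnegative")
  colnames(counts) <- spNames

  rxns <- model@reactions
  nR <- length(rxns)
  dep <- buildEventDeps(mesh, model)
  rOrder <- vapply(rxns, reactionOrder, numeric(1L))
  rS1 <- integer(nR); rS2 <- integer(nR)
  rDeltaSp <- vector("list", nR); rDeltaVal <- vector("list", nR)
  cPerTet <- matrix(0, nT, nR)
  for (r in seq_len(nR)) {
    rx <- rxns[[r]]
    lhsIdx <- match(names(rx$lhs), spNames)
    if (rOrder[r] == 1) {
      rS1[r] <- lhsIdx[1L]; rS2[r] <- 0L
    } else if (length(rx$lhs) == 2L) {
      rS1[r] <- lhsIdx[1L]; rS2[r] <- lhsIdx[2L]
    } else {
      rS1[r] <- rS2[r] <- lhsIdx[1L]
    }
    all <- union(names(rx$lhs), names(rx$rhs))
    net <- sapply(all, function(s)
      sum(rx$rhs[names(rx$rhs) == s]) - sum(rx$lhs[names(rx$lhs) == s]))
    keep <- net != 0
    rDeltaSp[[r]] <- match(all[keep], spNames) - 1L
    rDeltaVal[[r]] <- as.integer(net[keep])
    cPerTet[, r] <- scaledRateConstant(rx$k, rOrder[r], geom@volumes)
  }
  nb <- mesh@neighbors
  tables <- list(
    rOrder = as.integer(rOrder),
    rS1 = rS1 - 1L, rS2 = rS2 - 1L,
    rDeltaSp = rDeltaSp, rDeltaVal = rDeltaVal,
    cPerTet = cPerTet,
    diffSp = rates@speciesIndex - 1L,
    dTot = rates@dTotal,
    neighTet = matrix(as.integer(ifelse(nb == NO_NEIGHBOR, -1L, nb - 1L)),
                      nT, 4L),
    G = rates@geomFactor,
    deps = lapply(dep$deps, function(v) v - 1L),
    nLoc = dep$nLoc)
  new("SSAProblem", mesh = mesh, geometry = geom, model = model,
      rates = rates, init = counts, tables = tables)
}

#' Deterministic uniform placement of molecules
#'
#' Apportions whole-mesh totals over tets proportionally to tet volume using
#' largest-remainder rounding, so per-species totals are preserved exactly
#' and placement is deterministic.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param totals named numeric vector of whole-mesh molecule totals.
#' @param geom optional precomputed \linkS4class{MeshGeometry}.
#' @param species optional full species name vector (columns of the result);
#'   defaults to \code{names(totals)}.
#' @return integer matrix, tets x species.
#' @export
uniformInit <- function(mesh, totals, geom = NULL, species = NULL) {
  if (is.null(geom)) geom <- meshGeometry(mesh)
  if (is.null(species)) species <- names(totals)
  v <- geom@volumes
  w <- v / sum(v)
  counts <- matrix(0L, nTets(mesh), length(species),
                   dimnames = list(NULL, species))
  for (s in names(totals)) {
    n <- totals[[s]]
    if (is.na(match(s, species))) stop("unknown species in totals: ", s)
    exact <- n * w
    base <- floor(exact)
    left <- round(n - sum(base))
    if (left > 0) {
      extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
      base[extra] <- base[extra] + 1
    }
    counts[, s] <- as.integer(base)
  }
  counts
}

#' Problem accessors
#' @param problem an \linkS4class{SSAProblem}.
#' @return the stored component.
#' @export
problemMesh <- function(problem) problem@mesh

#' @rdname problemMesh
#' @export
problemModel <- function(problem) problem@model

#' @rdname problemMesh
#' @export
problemRates <- function(problem) problem@rates

#' @rdname problemMesh
#' @export
initialCounts <- function(problem) problem@init

setMethod("show", "SSAProblem", function(object) {
  cat("SSAProblem:", nTets(object@mesh), "tets,",
      nrow(object@model@species), "species,",
      length(object@model@reactions), "reactions,",
      sum(object@init), "molecules\n")
})
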