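## ssa_exact: event indexing, update dependency lists, and a vectorized
## reference propensity computation used to audit the incremental solvers.
##
## Event layout (shared with the C++ cores): per tet, locals 1..nR are
## reaction instances in model order, locals nR+1..nR+nD are diffusion
## instances, one per diffusive species (the destination neighbour is drawn
## at fire time). Global event id = (tet - 1) * (nR + nD) + local, 1-based
## in R, 0-based across the C++ boundary.

eventLayout <- function(model) {
  nR <- length(model@reactions)
  diffusive <- which(model@species$D > 0)
  list(nR = nR, nD = length(diffusive), nLoc = nR + length(diffusive),
       diffIdx = as.integer(diffusive),
       diffNames = model@species$name[diffusive])
}

#' Event ids for a (tet, local-event) pair
#'
#' @param tet tet index (1-based).
#' @param local local event index (1-based; reactions first, then one
#'   diffusion slot per diffusive species).
#' @param nLoc number of local events per tet.
#' @return 1-based global event id.
#' @export
eventId <- function(tet, local, nLoc) (tet - 1L) * nLoc + local

#' Build update dependency lists for all kinetic events
#'
#' For every reaction instance: the events in its own tet whose propensity
#' reads a species the reaction changes (a reaction only affects molecule
#' state in its own tetrahedron). For every diffusion instance: the
#' dependent events of the moved species in the source tet and in every
#' face-neighbour tet (the destination is drawn at fire time, so the list is
#' closed over all possible destinations).
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param model a \linkS4class{ReactionModel}.
#' @return a list with \code{deps} (per event, 1-based ids of events to
#'   refresh after it fires), \code{events} (data.frame describing each
#'   event) and the layout constants \code{nR}, \code{nD}, \code{nLoc}.
#' @export
buildEventDeps <- function(mesh, model) {
  lay <- eventLayout(model)
  nR <- lay$nR; nD <- lay$nD; nLoc <- lay$nLoc
  nT <- nTets(mesh)
  spNames <- model@species$name
  rxns <- model@reactions
  ## per reaction: species with nonzero net change (indices into species)
  netChange <- lapply(rxns, function(r) {
    all <- union(names(r$lhs), names(r$rhs))
    net <- sapply(all, function(s)
      sum(r$rhs[names(r$rhs) == s]) - sum(r$lhs[names(r$lhs) == s]))
    match(all[net != 0], spNames)
  })
  reactants <- lapply(rxns, function(r) match(names(r$lhs), spNames))
  ## localDeps[[s]]: local event indices whose propensity reads species s
  localDeps <- lapply(seq_along(spNames), function(s) {
    rs <- which(vapply(reactants, function(x) s %in% x, logical(1L)))
    ds <- which(lay$diffIdx == s)
    c(rs, if (length(ds)) nR + ds)
  })
  ## per reaction: local events to refresh in the same tet
  rxnLocal <- lapply(seq_len(nR), function(r)
    sort(unique(unlist(localDeps[netChange[[r]]]))))
  ## per diffusive species: local events to refresh in any affected tet
  diffLocal <- lapply(seq_len(nD), function(j) localDeps[[lay$diffIdx[j]]])
  nb <- mesh@neighbors
  deps <- vector("list", nT * nLoc)
  for (tet in seq_len(nT)) {
    base <- (tet - 1L) * nLoc
    for (r in seq_len(nR))
      deps[[base + r]] <- base + rxnLocal[[r]]
    if (nD) {
      tets <- c(tet, nb[tet, nb[tet, ] != NO_NEIGHBOR])
      for (j in seq_len(nD)) {
        loc <- diffLocal[[j]]
        deps[[base + nR + j]] <-
          sort(as.integer(outer(loc, (tets - 1L) * nLoc, `+`)))
      }
    }
  }
  events <- data.frame(
    id = seq_len(nT * nLoc),
    tet = rep(seq_len(nT), each = nLoc),
    kind = rep(c(rep("reaction", nR), rep("diffusion", nD)), nT),
    what = rep(c(if (nR) paste0("rxn", seq_len(nR)), lay$diffNames), nT),
    stringsAsFactors = FALSE)
  list(deps = deps, events = events, nR = nR, nD = nD, nLoc = nLoc,
       diffIdx = lay$diffIdx, diffNames = lay$diffNames)
}

#' Reference propensity table (full recomputation)
#'
#' Computes every kinetic event's propensity directly from a count matrix,
#' independently of the incremental dependency-driven updates maintained by
#' the solvers. Used to audit those updates.
#'
#' @param problem an \linkS4class{SSAProblem}.
#' @param counts integer matrix, tets x species.
#' @return numeric vector of propensities (1/s), one per event id.
#' @export
eventPropensities <- function(problem, counts) {
  tbl <- problem@tables
  nR <- length(tbl$rOrder); nD <- length(tbl$diffSp)
  nLoc <- nR + nD
  nT <- nrow(counts)
  a <- numeric(nT * nLoc)
  for (r in seq_len(nR)) {
    s1 <- tbl$rS1[r] + 1L; s2 <- tbl$rS2[r] + 1L
    p <- if (tbl$rOrder[r] == 1L) {
      tbl$cPerTet[, r] * counts[, s1]
    } else if (s1 == s2) {
      tbl$cPerTet[, r] * counts[, s1] * (counts[, s1] - 1) / 2
    } else {
      tbl$cPerTet[, r] * counts[, s1] * counts[, s2]
    }
    a[(seq_len(nT) - 1L) * nLoc + r] <- p
  }
  for (j in seq_len(nD)) {
    s <- tbl$diffSp[j] + 1L
    a[(seq_len(nT) - 1L) * nLoc + nR + j] <- counts[, s] * tbl$dTot[, j]
  }
  a
}
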