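## partition_parallel: the rank main loop on virtual ranks.
##
## A deterministic round-robin scheduler executes every rank's window step
## ({reaction SSA window; diffusion operator; send buffers}) followed by the
## exchange phase (each rank applies exactly one — possibly empty — buffer
## from each neighbour rank per window). Each rank draws from its own RNG
## stream, derived from (master seed, rank), so the full protocol, including
## stale-marker resets, is exercised in a single process. A message-passing
## backend would implement the identical per-rank step contract; ranks only
## ever exchange buffers with face-adjacent ranks.

#' Run the partition-parallel operator-splitting loop on virtual ranks
#'
#' With a single rank the protocol degenerates and the trajectory is
#' bitwise identical to \code{\link{runOpsplit}} at equal seed. Per-window
#' conservation (sent totals equal applied totals) and the buffer size bound
#' are asserted every window when \code{check = TRUE}.
#'
#' @inheritParams runExact
#' @param partition a \linkS4class{MeshPartition}; its rank count defines
#'   the virtual ranks.
#' @param check assert protocol invariants every window (cheap; default
#'   TRUE).
#' @return a \linkS4class{SimResult}; \code{info} carries tau, the window
#'   count, and a \code{timing} data.frame (per rank: Tcomp, Tsync, Tidle,
#'   Ttotal; idle time is structurally ~0 for in-process virtual ranks and
#'   is reported as measured).
#' @export
runParallel <- function(problem, partition, tEnd, seed, recordInterval = NULL,
                        init = NULL, check = TRUE) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  mesh <- problem@mesh
  if (length(partition@rankOf) != nTets(mesh))
    stop("configuration error: partition maps ", length(partition@rankOf),
         " tets but the mesh has ", nTets(mesh))
  nRanks <- partition@nRanks
  ## tau is a global minimum over ranks' local minima; on virtual ranks the
  ## min-reduction collapses to the global computation
  tau <- computeTau(problem@rates)
  recordTimes <- recordGrid(tEnd, recordInterval)
  counts <- copyCounts(if (is.null(init)) problem@init else init)
  nT <- nrow(counts); S <- ncol(counts)
  rankOf0 <- partition@rankOf           # 0-based, for C++
  hosted0 <- lapply(seq_len(nRanks) - 1L, function(r) which(rankOf0 == r) - 1L)
  nbRanks <- lapply(seq_len(nRanks) - 1L,
                    function(r) neighborRanks(mesh, partition, r))
  ## buffer size bound per (source rank, dest rank): remotely hosted
  ## neighbour tets x diffusive species
  nDiff <- length(problem@tables$diffSp)
  remoteNbTets <- matrix(0L, nRanks, nRanks)
  nb <- mesh@neighbors
  for (r in seq_len(nRanks)) {
    ht <- which(rankOf0 == r - 1L)
    js <- unique(as.vector(nb[ht, , drop = FALSE]))
    js <- js[js != NO_NEIGHBOR]
    js <- js[rankOf0[js] != r - 1L]
    if (length(js))
      for (q in unique(rankOf0[js]))
        remoteNbTets[r, q + 1L] <- sum(rankOf0[js] == q)
  }
  ## persistent per (source, dest) buffers: stale markers survive flushes
  buffers <- lapply(seq_len(nRanks), function(r)
    setNames(lapply(nbRanks[[r]], function(q) newRemoteChangeBuffer()),
             as.character(nbRanks[[r]])))
  rng <- rankRngStates(seed, nRanks)
  timing <- matrix(0, nRanks, 3L,
                   dimnames = list(NULL, c("Tcomp", "Tsync", "Tidle")))
  nrec <- length(recordTimes)
  records <- array(0L, c(nrec, nT, S))
  recIdx <- 1L
  if (nrec && recordTimes[1L] <= 0) {
    records[1L, , ] <- counts
    recIdx <- 2L
  }
  t <- 0
  nWindows <- 0L
  eps <- 1e-12
  while (t < tEnd - eps) {
    w <- tau
    if (recIdx <= nrec) w <- min(w, recordTimes[recIdx] - t)
    w <- min(w, tEnd - t)
    sentTotal <- 0L
    ## --- per-rank computation phase (reaction window + diffusion operator)
    for (r in seq_len(nRanks)) {
      restoreRng(rng, r)
      t0 <- proc.time()[[3L]]
      occ <- cpp_reaction_window(counts, problem@tables, hosted0[[r]], w)
      rem <- cpp_diffusion_step(counts, occ, problem@tables, hosted0[[r]],
                                rankOf0, r - 1L)
      saveRng(rng, r)
      ## register outbound changes (part of the diffusion operator)
      if (nrow(rem)) {
        for (i in seq_len(nrow(rem))) {
          destTet <- rem[i, 1L] + 1L
          q <- rankOf0[destTet]
          buf <- buffers[[r]][[as.character(q)]]
          if (is.null(buf))
            stop("protocol error: rank ", r - 1L,
                 " produced a change for non-neighbour rank ", q)
          registerRemoteChange(buf, destTet, rem[i, 2L] + 1L, rem[i, 3L])
        }
        sentTotal <- sentTotal + sum(rem[, 3L])
      }
      timing[r, "Tcomp"] <- timing[r, "Tcomp"] + (proc.time()[[3L]] - t0)
    }
    ## --- exchange phase: every rank applies one buffer per neighbour
    appliedTotal <- 0L
    for (r in seq_len(nRanks)) {
      t0 <- proc.time()[[3L]]
      for (q in nbRanks[[r]]) {
        buf <- buffers[[q + 1L]][[as.character(r - 1L)]]
        if (is.null(buf))
          stop("deadlock timeout error: rank ", r - 1L,
               " missing buffer from rank ", q, " at window ", nWindows)
        if (check) {
          stopifnot(bufferSize(buf) <= remoteNbTets[q + 1L, r] * nDiff)
        }
        entries <- flushBuffer(buf)
        if (nrow(entries)) {
          if (check && any(rankOf0[entries[, 1L]] != r - 1L))
            stop("protocol error: buffer entry for a tet not hosted by rank ",
                 r - 1L)
          for (i in seq_len(nrow(entries)))
            counts[entries[i, 1L], entries[i, 2L]] <-
              counts[entries[i, 1L], entries[i, 2L]] + entries[i, 3L]
          appliedTotal <- appliedTotal + sum(entries[, 3L])
        }
      }
      timing[r, "Tsync"] <- timing[r, "Tsync"] + (proc.time()[[3L]] - t0)
    }
    if (check && sentTotal != appliedTotal)
      stop("protocol conservation violated: sent ", sentTotal,
           " != applied ", appliedTotal)
    t <- t + w
    nWindows <- nWindows + 1L
    while (recIdx <= nrec && recordTimes[recIdx] <= t + eps) {
      records[recIdx, , ] <- counts
      recIdx <- recIdx + 1L
    }
  }
  while (recIdx <= nrec) {
    records[recIdx, , ] <- counts
    recIdx <- recIdx + 1L
  }
  timingDf <- data.frame(rank = seq_len(nRanks) - 1L, timing)
  timingDf$Ttotal <- timingDf$Tcomp + timingDf$Tsync + timingDf$Tidle
  newSimResult(problem, recordTimes, records, t, NA_real_,
               info = list(solver = "parallel", seed = seed, tau = tau,
                           nWindows = nWindows, nRanks = nRanks,
                           timing = timingDf, finalCounts = counts))
}
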