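## ssa_exact and opsplit_core solver front ends.

#' Diffusion time window
#'
#' The constant operator-splitting window: the minimum over every diffusive
#' species S and tet of 1 / d_S,tet. Fully determined by model and geometry,
#' computed once at initialization, and never changed during a run.
#'
#' @param rates a \linkS4class{DiffusionRateTable}.
#' @return tau (s).
#' @export
computeTau <- function(rates) {
  d <- rates@dTotal
  d <- d[d > 0]
  if (!length(d))
    stop("configuration error: no positive diffusion rate anywhere; ",
         "use the pure-reaction exact solver (runExact) instead")
  1 / max(d)
}

#' Run the exact spatial SSA reference solver
#'
#' Event-by-event simulation of the full reaction-diffusion jump process,
#' with either direct-method selection (hierarchical tet-then-event search)
#' or composition-rejection selection (power-of-two propensity groups,
#' rejection sampling within a group). Propensities are maintained
#' incrementally via the update dependency lists. When total propensity
#' reaches zero the clock jumps to the horizon.
#'
#' @param problem an \linkS4class{SSAProblem}.
#' @param tEnd run horizon (s).
#' @param seed integer seed (required; all randomness flows from it).
#' @param method \code{"direct"} or \code{"cr"}.
#' @param recordInterval recording cadence (s); records at 0, dt, 2dt, ...
#'   up to tEnd. NULL records only at 0 and tEnd.
#' @param maxSteps optional cap on the number of events (default unlimited).
#' @param init optional count matrix overriding the problem's initial state.
#' @return a \linkS4class{SimResult}.
#' @export
runExact <- function(problem, tEnd, seed, method = c("direct", "cr"),
                     recordInterval = NULL, maxSteps = Inf, init = NULL) {
  method <- match.arg(method)
  if (missing(seed) || is.null(seed)) stop("seed is required")
  recordTimes <- recordGrid(tEnd, recordInterval)
  counts <- copyCounts(if (is.null(init)) problem@init else init)
  set.seed(as.integer(seed))
  res <- cpp_run_exact(counts, problem@tables, 0, tEnd, recordTimes,
                       if (method == "cr") 1L else 0L,
                       as.double(maxSteps), 1000000L)
  newSimResult(problem, recordTimes, res$records, res$t, res$nSteps,
               info = list(solver = paste0("ssa-", method), seed = seed,
                           propensities = res$propensities,
                           eventCounts = res$eventCounts,
                           finalCounts = res$counts))
}

#' Occupancy-expected leaver count
#'
#' The diffusion operator's per-(tet, species) draw: expected leavers
#' mu = meanOcc * dTotal * tau, clamped to the available count, then
#' stochastically rounded (floor(mu) + Bernoulli(frac(mu))). Always in
#' [0, nNow]. This wraps the exact primitive used inside the solvers.
#'
#' @param meanOcc mean occupancy over the window (molecules).
#' @param nNow molecules available at the window end.
#' @param dTotal total local diffusion rate d_S,tet (1/s).
#' @param tau window length (s).
#' @param n number of draws.
#' @return integer vector of leaver counts.
#' @export
sampleLeavers <- function(meanOcc, nNow, dTotal, tau, n = 1L) {
  cpp_sample_leavers(meanOcc, nNow, dTotal, tau, as.integer(n))
}

#' Run one reaction SSA window (exported for inspection)
#'
#' Executes the reaction-only SSA over a window and returns the updated
#' counts together with the per-(tet, species) occupancy integrals
#' (molecule * s; divide by the window length for mean occupancy).
#'
#' @param problem an \linkS4class{SSAProblem}.
#' @param counts integer count matrix (tets x species).
#' @param window window length (s).
#' @param seed integer seed.
#' @return list with \code{counts} and \code{occupancy}.
#' @export
reactionWindow <- function(problem, counts, window, seed) {
  counts <- copyCounts(counts)
  set.seed(as.integer(seed))
  occ <- cpp_reaction_window(counts, problem@tables,
                             seq_len(nrow(counts)) - 1L, window)
  list(counts = counts, occupancy = occ)
}

#' Run one diffusion operator step (exported for inspection)
#'
#' @param problem an \linkS4class{SSAProblem}.
#' @param counts integer count matrix (tets x species); typically the output
#'   of \code{\link{reactionWindow}}.
#' @param occupancy occupancy integral matrix from the same window.
#' @param seed integer seed.
#' @return updated count matrix.
#' @export
diffusionStep <- function(problem, counts, occupancy, seed) {
  counts <- copyCounts(counts)
  set.seed(as.integer(seed))
  cpp_diffusion_step(counts, occupancy, problem@tables,
                     seq_len(nrow(counts)) - 1L, integer(), 0L)
  counts
}

#' Run the operator-splitting solver (single rank)
#'
#' Alternates a reaction-only SSA window of length tau (the constant
#' diffusion time window from \code{\link{computeTau}}) with the
#' occupancy-based multinomial diffusion operator, until the horizon.
#' Windows are shortened to land exactly on recording times and on tEnd;
#' the leaver expectation scales linearly with the shortened window, so the
#' mean diffusive flux is preserved.
#'
#' @inheritParams runExact
#' @return a \linkS4class{SimResult} (info carries tau and window count).
#' @export
runOpsplit <- function(problem, tEnd, seed, recordInterval = NULL,
                       init = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  tau <- computeTau(problem@rates)
  recordTimes <- recordGrid(tEnd, recordInterval)
  counts <- copyCounts(if (is.null(init)) problem@init else init)
  nT <- nrow(counts); S <- ncol(counts)
  hosted0 <- seq_len(nT) - 1L
  rng <- rankRngStates(seed, 1L)
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
    restoreRng(rng, 1L)
    occ <- cpp_reaction_window(counts, problem@tables, hosted0, w)
    cpp_diffusion_step(counts, occ, problem@tables, hosted0, integer(), 0L)
    saveRng(rng, 1L)
    t <- t + w
    nWindows <- nWindows + 1L
    while (recIdx <= nrec && recordTimes[recIdx] <= t + eps) {
      records[recIdx, , ] <- counts
      recIdx <- recIdx + 1L
    }
  }
  while (recIdx <= nrec) {  # tEnd == 0 etc.
    records[recIdx, , ] <- counts
    recIdx <- recIdx + 1L
  }
  newSimResult(problem, recordTimes, records, t, NA_real_,
               info = list(solver = "opsplit", seed = seed, tau = tau,
                           nWindows = nWindows, finalCounts = counts))
}

## --- shared helpers ---------------------------------------------------------

recordGrid <- function(tEnd, recordInterval) {
  if (is.null(recordInterval)) {
    if (tEnd > 0) c(0, tEnd) else 0
  } else {
    if (recordInterval <= 0) stop("recordInterval must be > 0")
    if (recordInterval > tEnd && tEnd > 0)
      stop("record interval must be <= tEnd")
    grid <- seq(0, tEnd, by = recordInterval)
    if (tEnd - grid[length(grid)] > 1e-9 * max(tEnd, 1)) grid <- c(grid, tEnd)
    grid
  }
}

## force a fresh integer matrix the C++ cores may mutate in place
copyCounts <- function(counts) {
  out <- counts + 0L
  storage.mode(out) <- "integer"
  out
}

## Per-rank RNG streams: independent streams derived from the master seed,
## stored as swappable .Random.seed states so the C++ cores (which consume
## R's RNG) stay on their rank's stream.
rankRngStates <- function(seed, nRanks) {
  set.seed(as.integer(seed))
  rankSeeds <- sample.int(2147483646L, nRanks)
  env <- new.env()
  env$states <- vector("list", nRanks)
  for (r in seq_len(nRanks)) {
    set.seed(rankSeeds[r])
    env$states[[r]] <- get(".Random.seed", envir = globalenv())
  }
  env
}

restoreRng <- function(env, rank) {
  assign(".Random.seed", env$states[[rank]], envir = globalenv())
}

saveRng <- function(env, rank) {
  env$states[[rank]] <- get(".Random.seed", envir = globalenv())
}

newSimResult <- function(problem, times, records, finalTime, nSteps, info) {
  spNames <- problem@model@species$name
  if (!is.array(records) || length(dim(records)) != 3L)
    records <- array(records, c(length(times), nTets(problem@mesh),
                                length(spNames)))
  dimnames(records) <- list(NULL, NULL, spNames)
  new("SimResult", times = as.numeric(times), counts = records,
      species = spNames, finalTime = finalTime, nSteps = as.numeric(nSteps),
      info = info)
}

#' SimResult accessors
#' @param result a \linkS4class{SimResult}.
#' @return recording times, the counts array, or per-time whole-mesh totals.
#' @export
recordTimes <- function(result) result@times

#' @rdname recordTimes
#' @export
countsArray <- function(result) result@counts

#' @rdname recordTimes
#' @export
speciesTotals <- function(result) {
  tot <- apply(result@counts, c(1L, 3L), sum)
  dimnames(tot) <- list(NULL, result@species)
  tot
}

setMethod("show", "SimResult", function(object) {
  cat("SimResult (", object@info$solver %||% "?", "): ",
      dim(object@counts)[2L], " tets x ", length(object@species),
      " species, ", length(object@times), " records, t = ",
      format(object@finalTime), " s\n", sep = "")
})
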