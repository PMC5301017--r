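## fixtures_validation: benchmark fixtures and the statistical comparison
## harness used to check the approximate solvers against the exact SSA.

#' Build a benchmark problem at a molecule-density scale
#'
#' The bundled benchmark model on a generated cuboid mesh, with every
#' initial total multiplied by \code{densityScale} (rounded to integers) and
#' molecules placed uniformly by volume. Scale 1 totals 55,000 molecules;
#' 0.1 and 10 are the standard low/high-density variants.
#'
#' @param densityScale positive multiplier for the initial totals.
#' @param meshCounts cells per axis for the generated mesh.
#' @param dims box extents (um), default the 10 x 10 x 100 um benchmark box.
#' @return an \linkS4class{SSAProblem}.
#' @export
makeBenchmark <- function(densityScale = 1, meshCounts = c(5, 5, 50),
                          dims = c(10, 10, 100)) {
  if (densityScale <= 0) stop("densityScale must be positive")
  model <- benchmarkModel()
  totals <- round(initialTotals(model) * densityScale)
  if (all(totals == 0))
    stop("densityScale ", densityScale, " yields all-zero initial counts")
  mesh <- cuboidMesh(dims, meshCounts)
  ssaProblem(model, mesh, totals)
}

solverRunner <- function(solver, problem, partition = NULL, method = "direct") {
  switch(solver,
    ssa = function(tEnd, seed, recordInterval)
      runExact(problem, tEnd, seed, method = method,
               recordInterval = recordInterval),
    opsplit = function(tEnd, seed, recordInterval)
      runOpsplit(problem, tEnd, seed, recordInterval = recordInterval),
    parallel = function(tEnd, seed, recordInterval)
      runParallel(problem, partition, tEnd, seed,
                  recordInterval = recordInterval),
    stop("unknown solver: ", solver))
}

#' Compare two solvers on the same problem across seeds
#'
#' Runs both solvers with \code{nSeeds} paired independent seeds and, for
#' every (species, recorded time), summarizes whole-mesh totals from each
#' solver (mean and normal 95\% CI over seeds) and tests distributional
#' agreement with a two-sided two-sample Kolmogorov-Smirnov test across
#' seeds; p-values are Benjamini-Hochberg adjusted across the
#' (species x time) grid. A spatial summary (the center-of-mass z coordinate
#' per run) is compared the same way in the \code{spatial} component.
#'
#' @param problem an \linkS4class{SSAProblem}.
#' @param solverA,solverB \code{"ssa"}, \code{"opsplit"} or
#'   \code{"parallel"}.
#' @param nSeeds number of independent seeds per solver.
#' @param tEnd horizon (s).
#' @param recordInterval recording cadence (s).
#' @param seed master seed from which per-run seeds are derived.
#' @param partitionA,partitionB partitions (parallel solver only).
#' @param methodA,methodB exact-SSA selection method ("direct"/"cr").
#' @param sharedSeeds run both solvers with the same seed sequence (useful
#'   for identity checks); default FALSE (independent seeds).
#' @return list with \code{totals} and \code{spatial} data.frames
#'   (columns species, time, meanA, loA, hiA, meanB, loB, hiB, ks, p, pAdj,
#'   nSeeds) and the raw per-seed total arrays.
#' @export
compareSolvers <- function(problem, solverA, solverB, nSeeds, tEnd,
                           recordInterval, seed = 1,
                           partitionA = NULL, partitionB = NULL,
                           methodA = "direct", methodB = "direct",
                           sharedSeeds = FALSE) {
  runA <- solverRunner(solverA, problem, partitionA, methodA)
  runB <- solverRunner(solverB, problem, partitionB, methodB)
  set.seed(seed)
  seeds <- sample.int(2147483646L, 2L * nSeeds)
  seedsA <- seeds[seq_len(nSeeds)]
  seedsB <- if (sharedSeeds) seedsA else seeds[nSeeds + seq_len(nSeeds)]
  collect <- function(run, seeds) {
    tots <- NULL; spat <- NULL
    bz <- meshGeometry(problem@mesh)@barycenters[, 3L]
    for (i in seq_along(seeds)) {
      r <- run(tEnd, seeds[i], recordInterval)
      tot <- speciesTotals(r)                       # time x species
      cz <- apply(r@counts, c(1L, 3L), function(v)  # center of mass in z
        if (sum(v) > 0) sum(v * bz) / sum(v) else NA_real_)
      if (is.null(tots)) {
        tots <- array(0, c(length(seeds), nrow(tot), ncol(tot)))
        spat <- array(0, c(length(seeds), nrow(tot), ncol(tot)))
        times <- recordTimes(r)
      }
      tots[i, , ] <- tot
      spat[i, , ] <- cz
    }
    list(tots = tots, spat = spat, times = times)
  }
  A <- collect(runA, seedsA)
  B <- collect(runB, seedsB)
  if (length(A$times) != length(B$times) || any(A$times != B$times))
    stop("mismatched recording grids between solvers")
  summarize <- function(arrA, arrB) {
    sp <- problem@model@species$name
    out <- expand.grid(time = A$times, species = sp,
                       stringsAsFactors = FALSE)[, 2:1]
    n <- dim(arrA)[1L]
    stats <- lapply(seq_len(nrow(out)), function(k) {
      ti <- match(out$time[k], A$times)
      si <- match(out$species[k], sp)
      xa <- arrA[, ti, si]; xb <- arrB[, ti, si]
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      ciA <- 1.96 * sd(xa) / sqrt(length(xa))
      ciB <- 1.96 * sd(xb) / sqrt(length(xb))
      ks <- if (length(xa) && length(xb))
        suppressWarnings(ks.test(xa, xb)) else list(statistic = NA, p.value = NA)
      c(meanA = mean(xa), loA = mean(xa) - ciA, hiA = mean(xa) + ciA,
        meanB = mean(xb), loB = mean(xb) - ciB, hiB = mean(xb) + ciB,
        ks = unname(ks$statistic), p = unname(ks$p.value))
    })
    out <- cbind(out, do.call(rbind, stats))
    out$pAdj <- p.adjust(out$p, method = "BH")
    out$nSeeds <- n
    out
  }
  totals <- summarize(A$tots, B$tots)
  spatial <- summarize(A$spat, B$spat)
  list(totals = totals, spatial = spatial,
       rawA = A, rawB = B,
       solvers = c(solverA, solverB), nSeeds = nSeeds)
}

#' Write a ComparisonResult to CSV + JSON summary
#'
#' @param cmp result of \code{\link{compareSolvers}}.
#' @param prefix output path prefix.
#' @return invisibly the two paths.
#' @export
writeComparison <- function(cmp, prefix) {
  csv <- paste0(prefix, "_comparison.csv")
  jsn <- paste0(prefix, "_comparison.json")
  both <- rbind(cbind(what = "totals", cmp$totals),
                cbind(what = "spatial", cmp$spatial))
  write.csv(both, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    solvers = cmp$solvers, nSeeds = cmp$nSeeds,
    minAdjustedP = list(totals = min(cmp$totals$pAdj, na.rm = TRUE),
                        spatial = min(cmp$spatial$pAdj, na.rm = TRUE)),
    ciOverlap = mean(ciOverlap(cmp$totals))), jsn,
    auto_unbox = TRUE, digits = NA)
  invisible(c(csv, jsn))
}

#' Fraction-of-grid CI overlap helper
#'
#' TRUE where the two solvers' 95\% confidence intervals for the mean
#' overlap.
#'
#' @param totals a \code{totals} data.frame from
#'   \code{\link{compareSolvers}}.
#' @return logical vector along the (species x time) grid.
#' @export
ciOverlap <- function(totals) {
  totals$loA <= totals$hiB & totals$loB <= totals$hiA
}
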