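## simcontrol_io: run configuration, recorder output, timing metrics.

#' Read / write / validate a run configuration
#'
#' Config schema (YAML or JSON): \describe{
#'   \item{model}{path to a model JSON file, or \code{"benchmark"} for the
#'     bundled benchmark model.}
#'   \item{mesh}{either \code{list(generate = list(dims, counts))} or
#'     \code{list(file = path)}.}
#'   \item{partition}{optional; \code{list(linear = c(px, py, pz))} or
#'     \code{list(file = path)}. Required for solver "parallel".}
#'   \item{solver}{"ssa", "opsplit" or "parallel".}
#'   \item{method}{for "ssa": "direct" (default) or "cr".}
#'   \item{seed}{integer, required.}
#'   \item{tEnd}{run horizon (s).}
#'   \item{recordInterval}{recording cadence (s), <= tEnd.}
#'   \item{output}{output path prefix (writes <prefix>_counts.csv and
#'     <prefix>_timing.json).}
#' }
#'
#' @param path config file (.yaml/.yml or .json).
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg config list.
#' @param format \code{"yaml"} or \code{"json"}.
#' @export
writeRunConfig <- function(cfg, path, format = c("yaml", "json")) {
  format <- match.arg(format)
  if (format == "yaml") yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname readRunConfig
#' @export
validateRunConfig <- function(cfg) {
  need <- function(field) {
    if (is.null(cfg[[field]]))
      stop("config error: missing required field '", field, "'")
    cfg[[field]]
  }
  solver <- need("solver")
  if (!solver %in% c("ssa", "opsplit", "parallel"))
    stop("config error: field 'solver' must be ssa, opsplit or parallel")
  need("model"); need("mesh")
  seed <- need("seed")
  if (!is.numeric(seed) || seed != floor(seed))
    stop("config error: field 'seed' must be an integer")
  tEnd <- need("tEnd")
  if (!is.numeric(tEnd) || tEnd < 0)
    stop("config error: field 'tEnd' must be >= 0")
  if (!is.null(cfg$recordInterval) && tEnd > 0 &&
      cfg$recordInterval > tEnd)
    stop("config error: field 'recordInterval' must be <= tEnd")
  if (solver == "parallel" && is.null(cfg$partition))
    stop("config error: solver 'parallel' requires field 'partition'")
  cfg
}

## materialize config pieces
configModel <- function(cfg) {
  if (identical(cfg$model, "benchmark")) benchmarkModel()
  else readModel(cfg$model)
}

configMesh <- function(cfg) {
  m <- cfg$mesh
  if (!is.null(m$generate))
    cuboidMesh(as.numeric(m$generate$dims), as.integer(m$generate$counts))
  else if (!is.null(m$file)) readMesh(m$file)
  else stop("config error: mesh needs 'generate' or 'file'")
}

configPartition <- function(cfg, mesh) {
  p <- cfg$partition
  if (is.null(p)) return(NULL)
  if (!is.null(p$linear)) partitionLinear(mesh, as.integer(p$linear))
  else if (!is.null(p$file)) readPartition(p$file, nTets = nTets(mesh))
  else stop("config error: partition needs 'linear' or 'file'")
}

#' Run a simulation from a configuration
#'
#' Deterministic given (config, seed) on the virtual-rank backend. Writes
#' the counts recorder CSV and (for the parallel solver) a timing-report
#' JSON next to \code{output}, and returns the \linkS4class{SimResult}.
#' A structured log line records tau, rank count and iteration count.
#'
#' @param cfg config list or path to a config file.
#' @param quiet suppress the log line.
#' @return the \linkS4class{SimResult}, invisibly.
#' @export
runFromConfig <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  cfg <- validateRunConfig(cfg)
  model <- configModel(cfg)
  mesh <- configMesh(cfg)
  init <- if (!is.null(cfg$init)) unlist(cfg$init) else NULL
  problem <- ssaProblem(model, mesh, init)
  partition <- configPartition(cfg, mesh)
  res <- switch(cfg$solver,
    ssa = runExact(problem, cfg$tEnd, cfg$seed,
                   method = cfg$method %||% "direct",
                   recordInterval = cfg$recordInterval),
    opsplit = runOpsplit(problem, cfg$tEnd, cfg$seed,
                         recordInterval = cfg$recordInterval),
    parallel = runParallel(problem, partition, cfg$tEnd, cfg$seed,
                           recordInterval = cfg$recordInterval))
  if (!quiet) {
    tau <- res@info$tau
    message(sprintf(
      "[tetrasplit] solver=%s seed=%d tEnd=%g tau=%s windows=%s ranks=%s",
      cfg$solver, as.integer(cfg$seed), cfg$tEnd,
      if (is.null(tau)) "-" else format(tau),
      res@info$nWindows %||% "-", res@info$nRanks %||% 1L))
  }
  if (!is.null(cfg$output)) {
    writeCountsCSV(res, paste0(cfg$output, "_counts.csv"))
    writeCountsCSV(res, paste0(cfg$output, "_totals.csv"), aggregate = TRUE)
    if (!is.null(res@info$timing))
      jsonlite::write_json(res@info$timing,
                           paste0(cfg$output, "_timing.json"),
                           dataframe = "rows", digits = NA)
  }
  invisible(res)
}

#' Write the recorder CSV
#'
#' Per-tet records with header \code{time,tet,species,count}, or the
#' whole-compartment aggregate variant \code{time,species,count}.
#'
#' @param result a \linkS4class{SimResult}.
#' @param path output path (written atomically via a temp file).
#' @param aggregate write whole-mesh totals instead of per-tet counts.
#' @return invisibly \code{path}.
#' @export
writeCountsCSV <- function(result, path, aggregate = FALSE) {
  tmp <- paste0(path, ".tmp")
  if (aggregate) {
    tot <- speciesTotals(result)
    df <- data.frame(
      time = rep(result@times, times = ncol(tot)),
      species = rep(colnames(tot), each = nrow(tot)),
      count = as.vector(tot))
  } else {
    cnt <- result@counts
    d <- dim(cnt)
    df <- data.frame(
      time = rep(result@times, times = d[2L] * d[3L]),
      tet = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
      species = rep(result@species, each = d[1L] * d[2L]),
      count = as.vector(cnt))
  }
  write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Strong/weak scaling metrics from timing reports
#'
#' Speedup of p processes relative to q is S_p/q = T_q / T_p; strong
#' scaling efficiency is E_p/q = S_p/q * q / p. These are hardware-dependent
#' reporting quantities, not a correctness surface, and are marked as such
#' in the output.
#'
#' @param reports named list or data.frame mapping rank count p to total
#'   wall-clock time T_p (s); e.g. \code{data.frame(p = c(5, 20),
#'   Ttotal = c(100, 25))}.
#' @param q baseline rank count (must appear in \code{reports}).
#' @return data.frame with p, Ttotal, S (speedup vs q), E (efficiency),
#'   plus an attribute \code{note}.
#' @export
scalingReport <- function(reports, q) {
  df <- as.data.frame(reports)
  if (!all(c("p", "Ttotal") %in% names(df)))
    stop("reports needs columns 'p' and 'Ttotal'")
  if (nrow(df) < 2L) stop("need >= 2 reports with distinct rank counts")
  iq <- match(q, df$p)
  if (is.na(iq)) stop("missing baseline: no report with p = ", q)
  Tq <- df$Ttotal[iq]
  df$S <- Tq / df$Ttotal
  df$E <- df$S * q / df$p
  attr(df, "note") <- "hardware-dependent -- not an acceptance surface"
  df
}

#' Weak scaling efficiency E_k = T_(N,p) / T_(kN,kp)
#'
#' @param Tbase wall-clock time of the baseline (problem size N, p ranks).
#' @param Tscaled wall-clock time with size and ranks both scaled k-fold.
#' @return the efficiency ratio.
#' @export
weakScalingEfficiency <- function(Tbase, Tscaled) Tbase / Tscaled
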