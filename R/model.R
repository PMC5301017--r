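## model_core: biochemical model description and stochastic rate computation.

## Molecules per uM per um^3: N_A * 1e-6 mol/L * 1e-15 L/um^3 (CODATA-exact).
MOLECULES_PER_UM_UM3 <- 602.214076

#' Construct a reaction-diffusion model
#'
#' @param species data.frame with columns \code{name} and \code{D}
#'   (diffusion coefficient, um^2/s, >= 0; 0 = immobile).
#' @param reactions list of reactions, each a list with named integer
#'   stoichiometry vectors \code{lhs} and \code{rhs} and rate constant
#'   \code{k} (1/s for order one, 1/(uM s) for order two). Total reactant
#'   stoichiometry (the order) must be 1 or 2.
#' @param init optional named numeric vector of whole-mesh initial totals.
#' @return a \linkS4class{ReactionModel}.
#' @export
reactionModel <- function(species, reactions = list(), init = numeric()) {
  species <- as.data.frame(species)
  if (!all(c("name", "D") %in% names(species)))
    stop("species needs columns 'name' and 'D'")
  species$name <- as.character(species$name)
  if (anyDuplicated(species$name)) stop("species names must be unique")
  if (any(species$D < 0)) stop("diffusion coefficients must be >= 0")
  for (r in reactions) {
    if (!all(c("lhs", "rhs", "k") %in% names(r)))
      stop("each reaction needs lhs, rhs and k")
    stoich <- c(r$lhs, r$rhs)
    if (length(r$lhs) == 0L) stop("reactions must have at least one reactant")
    if (any(stoich <= 0) || any(stoich != floor(stoich)))
      stop("stoichiometries must be positive integers")
    ord <- sum(r$lhs)
    if (!ord %in% c(1, 2))
      stop("unsupported-order error: reaction order must be 1 or 2, got ", ord)
    refs <- unique(c(names(r$lhs), names(r$rhs)))
    miss <- setdiff(refs, species$name)
    if (length(miss))
      stop("reaction references undeclared species: ", paste(miss, collapse = ", "))
  }
  if (length(init)) {
    miss <- setdiff(names(init), species$name)
    if (length(miss))
      stop("init references undeclared species: ", paste(miss, collapse = ", "))
  }
  new("ReactionModel", species = species, reactions = reactions,
      init = init)
}

#' Model accessors
#' @param model a \linkS4class{ReactionModel}.
#' @return species data.frame / reaction list / species name vector.
#' @export
modelSpecies <- function(model) model@species

#' @rdname modelSpecies
#' @export
modelReactions <- function(model) model@reactions

#' @rdname modelSpecies
#' @export
speciesNames <- function(model) model@species$name

#' @rdname modelSpecies
#' @export
initialTotals <- function(model) model@init

reactionOrder <- function(r) sum(r$lhs)

setMethod("show", "ReactionModel", function(object) {
  cat("ReactionModel:", nrow(object@species), "species,",
      length(object@reactions), "reactions\n")
  fmt <- function(st) paste(ifelse(st > 1L, paste0(st, " "), ""),
                            names(st), sep = "", collapse = " + ")
  for (r in object@reactions)
    cat(" ", fmt(r$lhs), "->", fmt(r$rhs), " k =", r$k, "\n")
})

#' Volume-scaled per-event rate constant
#'
#' Converts a macroscopic rate constant to the per-event stochastic rate in a
#' compartment of volume \code{V}. First-order constants pass through;
#' second-order constants in 1/(uM s) are divided by (602.214076 * V), using
#' the exact conversion 1 uM um^3 = 602.214076 molecules.
#'
#' @param k rate constant (1/s for order 1, 1/(uM s) for order 2).
#' @param order reaction order, 1 or 2.
#' @param V compartment volume (um^3), > 0.
#' @return per-event rate c (1/s).
#' @export
scaledRateConstant <- function(k, order, V) {
  if (!order %in% c(1, 2))
    stop("unsupported-order error: order must be 1 or 2")
  if (any(!is.finite(V)) || any(V <= 0)) stop("V must be > 0")
  if (order == 1) rep_len(k, length(V)) else k / (MOLECULES_PER_UM_UM3 * V)
}

#' Mass-action reaction propensity
#'
#' a = c n_A for A -> ...; a = c n_A n_B for A + B -> ...;
#' a = c n_A (n_A - 1) / 2 for 2A -> ..., with c from
#' \code{\link{scaledRateConstant}}.
#'
#' @param reaction a reaction record (list with lhs, rhs, k).
#' @param counts named integer vector of molecule counts.
#' @param V compartment volume (um^3).
#' @return propensity (1/s).
#' @export
reactionPropensity <- function(reaction, counts, V) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  ord <- reactionOrder(reaction)
  c0 <- scaledRateConstant(reaction$k, ord, V)
  lhs <- reaction$lhs
  if (ord == 1) {
    c0 * counts[[names(lhs)[1L]]]
  } else if (length(lhs) == 2L) {
    c0 * counts[[names(lhs)[1L]]] * counts[[names(lhs)[2L]]]
  } else {
    n <- counts[[names(lhs)[1L]]]
    c0 * n * (n - 1) / 2
  }
}

#' Per-tet diffusion rate table
#'
#' For each interior face k of tet i and diffusive species S:
#' d_k = D_S * A_k / (h_k * V_i), the standard tetrahedral discretization of
#' Fickian diffusion with h the barycenter-to-barycenter distance; the local
#' total is d_S,tet = sum_k d_k. Immobile species (D = 0) are omitted.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param geom matching \linkS4class{MeshGeometry}.
#' @param model a \linkS4class{ReactionModel}.
#' @return a \linkS4class{DiffusionRateTable}.
#' @export
diffusionRates <- function(mesh, geom, model) {
  sp <- model@species
  keep <- which(sp$D > 0)
  gf <- geom@faceAreas / (geom@neighborDist * geom@volumes)
  gf[is.na(gf)] <- 0
  rs <- rowSums(gf)
  dTot <- outer(rs, sp$D[keep])
  if (!length(keep)) dTot <- matrix(0, nTets(mesh), 0L)
  colnames(dTot) <- sp$name[keep]
  new("DiffusionRateTable", species = sp$name[keep], D = sp$D[keep],
      speciesIndex = as.integer(keep), geomFactor = gf, dTotal = dTot)
}

#' @rdname diffusionRates
#' @param rates a \linkS4class{DiffusionRateTable}.
#' @export
diffusionTotals <- function(rates) rates@dTotal

#' The bundled benchmark reaction-diffusion model
#'
#' A 10-species, 4-reversible-reaction mass-action model widely used to
#' benchmark spatial SSA solvers: species A..J with diffusion coefficients
#' 100, 90, ..., 10 um^2/s and whole-mesh initial totals 1000, 2000, ...,
#' 10000 molecules (55,000 in total), with reversible pairs
#' A+B <-> C (kf 1000 1/(uM s), kb 100 1/s), C+D <-> E (100, 10),
#' F+G <-> H (10, 1) and H+I <-> J (1, 1). Reversible arrows are stored as
#' two irreversible records, giving 8 reaction records.
#'
#' @return a \linkS4class{ReactionModel} with initial totals attached.
#' @export
benchmarkModel <- function() {
  nm <- LETTERS[1:10]
  sp <- data.frame(name = nm, D = seq(100, 10, by = -10))
  init <- setNames(seq(1000, 10000, by = 1000), nm)
  rev2 <- function(a, b, c, kf, kb) {
    lhs <- setNames(c(1L, 1L), c(a, b))
    rhs <- setNames(1L, c)
    list(list(lhs = lhs, rhs = rhs, k = kf),
         list(lhs = rhs, rhs = lhs, k = kb))
  }
  rxns <- c(rev2("A", "B", "C", 1000, 100),
            rev2("C", "D", "E", 100, 10),
            rev2("F", "G", "H", 10, 1),
            rev2("H", "I", "J", 1, 1))
  reactionModel(sp, rxns, init)
}

#' Read / write a model description (JSON)
#'
#' Schema: \code{{species:[{name,D}], reactions:[{lhs,rhs,k}], init:{...}}}
#' with stoichiometry maps as JSON objects.
#'
#' @param path file path.
#' @return a \linkS4class{ReactionModel} (reader) or \code{path} (writer).
#' @export
readModel <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sp <- data.frame(
    name = vapply(x$species, function(s) as.character(s$name), character(1)),
    D = vapply(x$species, function(s) as.numeric(s$D), numeric(1)))
  stoich <- function(m) {
    v <- vapply(m, as.integer, integer(1))
    setNames(v, names(m))
  }
  reactions <- lapply(x$reactions, function(r)
    list(lhs = stoich(r$lhs), rhs = stoich(r$rhs), k = as.numeric(r$k)))
  init <- if (!is.null(x$init) && length(x$init))
    vapply(x$init, as.numeric, numeric(1)) else numeric()
  reactionModel(sp, reactions, init)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readModel
#' @param model a \linkS4class{ReactionModel}.
#' @export
writeModel <- function(model, path) {
  x <- list(
    species = model@species,
    reactions = lapply(model@reactions, function(r)
      list(lhs = as.list(r$lhs), rhs = as.list(r$rhs), k = r$k)),
    init = as.list(model@init))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
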