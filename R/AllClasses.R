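#' @useDynLib tetrasplit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats runif setNames ks.test p.adjust sd quantile chisq.test
#' @importFrom utils write.csv read.csv head tail
NULL

## Sentinel for "no neighbor across this face" in neighbor tables.
NO_NEIGHBOR <- -1L

#' Tetrahedral mesh
#'
#' An unstructured tetrahedral mesh: vertex coordinates (micrometres), tets as
#' rows of four vertex indices, and face-neighbour connectivity. Connectivity
#' is always rebuilt from the tet table (never trusted from a file), and every
#' tet is re-oriented to positive volume on construction.
#'
#' @slot vertices numeric matrix, one row per vertex, columns x, y, z (um).
#' @slot tets integer matrix, one row per tet, four 1-based vertex indices.
#' @slot neighbors integer matrix, one row per tet, four columns: the tet
#'   across the face opposite local vertex 1..4, or -1 for a boundary face.
#' @export
setClass("TetMesh", representation(
  vertices = "matrix",
  tets = "matrix",
  neighbors = "matrix"
))

#' Per-tet mesh geometry tables
#'
#' Geometric quantities entering local diffusion rates: tet volumes,
#' barycenters, shared-face areas and barycenter-to-barycenter distances.
#'
#' @slot volumes numeric, per-tet volume (um^3).
#' @slot barycenters numeric matrix, per-tet barycenter (um).
#' @slot faceAreas numeric matrix, per tet x local face, area of the face
#'   opposite local vertex f (um^2); NA for boundary faces.
#' @slot neighborDist numeric matrix, per tet x local face, distance between
#'   the two adjacent tets' barycenters (um); NA for boundary faces.
#' @export
setClass("MeshGeometry", representation(
  volumes = "numeric",
  barycenters = "matrix",
  faceAreas = "matrix",
  neighborDist = "matrix"
))

#' Biochemical reaction-diffusion model
#'
#' Species with diffusion coefficients and mass-action reactions of order one
#' or two. Reversible reactions are stored as two records. An optional named
#' vector of whole-mesh initial molecule totals may ride along.
#'
#' @slot species data.frame with columns \code{name} (character) and \code{D}
#'   (diffusion coefficient, um^2/s; 0 means immobile).
#' @slot reactions list of lists with elements \code{lhs}, \code{rhs} (named
#'   integer stoichiometry vectors) and \code{k} (rate constant; 1/s for order
#'   one, 1/(uM s) for order two).
#' @slot init named numeric vector of initial whole-mesh molecule totals
#'   (may be empty).
#' @export
setClass("ReactionModel", representation(
  species = "data.frame",
  reactions = "list",
  init = "numeric"
))

#' Per-tet diffusion rate table
#'
#' For every diffusive species S and tet, the per-neighbour first-exit rates
#' d_k = D * A_k / (h_k * V) (1/s) and their total d_S,tet. The geometry
#' factor A_k/(h_k V) is species independent and stored once.
#'
#' @slot species character, diffusive species names (D > 0).
#' @slot D numeric, their diffusion coefficients (um^2/s).
#' @slot speciesIndex integer, their column indices in the full species list.
#' @slot geomFactor numeric matrix, per tet x local face: A_k/(h_k*V_i)
#'   (1/um^2... net units 1/um^2 -> times D gives 1/s); 0 for boundary faces.
#' @slot dTotal numeric matrix, per tet x diffusive species: total rate
#'   d_S,tet (1/s).
#' @export
setClass("DiffusionRateTable", representation(
  species = "character",
  D = "numeric",
  speciesIndex = "integer",
  geomFactor = "matrix",
  dTotal = "matrix"
))

#' Mesh partition over simulation ranks
#'
#' Maps every tet to exactly one rank (0-based rank ids, matching MPI and
#' Metis .epart conventions).
#'
#' @slot rankOf integer, per-tet rank id in 0..nRanks-1.
#' @slot nRanks integer, number of ranks.
#' @export
setClass("MeshPartition", representation(
  rankOf = "integer",
  nRanks = "integer"
))

#' A fully assembled simulation problem
#'
#' Binds a model, mesh, geometry, diffusion rates, initial per-tet counts and
#' the precomputed solver tables (dependency lists, per-tet scaled rate
#' constants) consumed by the C++ cores.
#'
#' @slot mesh a \linkS4class{TetMesh}.
#' @slot geometry a \linkS4class{MeshGeometry}.
#' @slot model a \linkS4class{ReactionModel}.
#' @slot rates a \linkS4class{DiffusionRateTable}.
#' @slot init integer matrix, tets x species initial molecule counts.
#' @slot tables list of precomputed solver tables (internal layout).
#' @export
setClass("SSAProblem", representation(
  mesh = "ANY",
  geometry = "ANY",
  model = "ANY",
  rates = "ANY",
  init = "matrix",
  tables = "list"
))

#' Recorded simulation trajectory
#'
#' @slot times numeric, recording times (s).
#' @slot counts integer array \code{[time, tet, species]}.
#' @slot species character, species names.
#' @slot finalTime numeric, simulation time at exit (s).
#' @slot nSteps numeric, number of kinetic events executed (SSA solvers) or
#'   NA for window-based solvers.
#' @slot info list of solver metadata (tau, windows, timing, ...).
#' @export
setClass("SimResult", representation(
  times = "numeric",
  counts = "array",
  species = "character",
  finalTime = "numeric",
  nSteps = "numeric",
  info = "list"
))
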