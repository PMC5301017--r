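## Shared fixtures, all generated in code.

## a single regular tet: the unit right tetrahedron, V = 1/6
oneTetMesh <- function() {
  tetMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          rbind(1:4))
}

## two tets sharing the face {2,3,4}
twoTetMesh <- function() {
  tetMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 1)),
          rbind(1:4, c(2, 3, 4, 5)))
}

## immobile A -> B in one tet
conversionModel <- function(k = 2) {
  reactionModel(data.frame(name = c("A", "B"), D = c(0, 0)),
                list(list(lhs = c(A = 1L), rhs = c(B = 1L), k = k)))
}

## immobile A + B <-> C in one voxel
bindingModel <- function(kf = 1000, kb = 100) {
  reactionModel(data.frame(name = c("A", "B", "C"), D = c(0, 0, 0)),
                list(list(lhs = c(A = 1L, B = 1L), rhs = c(C = 1L), k = kf),
                     list(lhs = c(C = 1L), rhs = c(A = 1L, B = 1L), k = kb)))
}

## single diffusive species
freeDiffusionModel <- function(D = 100) {
  reactionModel(data.frame(name = "X", D = D))
}

## analytic stationary distribution of A+B<->C in one voxel of volume V:
## detailed balance gives pi(nC) prop. to (cf/cb)^nC * binomial depletion
## factors; returns the mean of nC.
cmeEquilibriumMeanC <- function(a0, b0, kf, kb, V) {
  cf <- kf / (602.214076 * V)
  nc <- 0:min(a0, b0)
  lw <- nc * log(cf / kb) +
    lfactorial(a0) - lfactorial(a0 - nc) +
    lfactorial(b0) - lfactorial(b0 - nc) - lfactorial(nc)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  sum(nc * w)
}

## independent brute-force propensity of every event, computed directly from
## first principles (not via the package's table machinery)
bruteForcePropensities <- function(model, mesh, counts) {
  geom <- meshGeometry(mesh)
  spn <- model@species$name
  rxns <- model@reactions
  diffusive <- which(model@species$D > 0)
  nLoc <- length(rxns) + length(diffusive)
  a <- numeric(nTets(mesh) * nLoc)
  nb <- meshNeighbors(mesh)
  for (t in seq_len(nTets(mesh))) {
    V <- geom@volumes[t]
    for (r in seq_along(rxns)) {
      cn <- setNames(as.numeric(counts[t, ]), spn)
      a[(t - 1L) * nLoc + r] <- reactionPropensity(rxns[[r]], cn, V)
    }
    for (j in seq_along(diffusive)) {
      s <- diffusive[j]
      dtot <- 0
      for (f in 1:4) {
        if (nb[t, f] == -1L) next
        A <- geom@faceAreas[t, f]
        h <- geom@neighborDist[t, f]
        dtot <- dtot + model@species$D[s] * A / (h * V)
      }
      a[(t - 1L) * nLoc + length(rxns) + j] <- counts[t, s] * dtot
    }
  }
  a
}
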