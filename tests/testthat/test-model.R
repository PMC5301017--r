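test_that("rate-constant scaling follows the molecule-per-uM-um3 conversion", {
  expect_equal(scaledRateConstant(100, 1, 5), 100)          # order 1: volume free
  expect_equal(scaledRateConstant(1000, 2, 1), 1000 / 602.214076,
               tolerance = 1e-12)                           # ~1.66054 per pair
  expect_error(scaledRateConstant(1, 2, 0), "V must be > 0")
  expect_error(scaledRateConstant(1, 3, 1), "unsupported-order")
})

test_that("mass-action propensities cover all order-1/order-2 cases", {
  AB <- list(lhs = c(A = 1L, B = 1L), rhs = c(C = 1L), k = 1000)
  expect_equal(reactionPropensity(AB, c(A = 0, B = 50, C = 0), 1), 0)
  expect_equal(reactionPropensity(AB, c(A = 10, B = 20, C = 0), 1),
               1000 / 602.214076 * 200, tolerance = 1e-12)  # ~332.11 1/s
  dimer <- list(lhs = c(A = 2L), rhs = c(B = 1L), k = 10)
  expect_equal(reactionPropensity(dimer, c(A = 1, B = 0), 1), 0)
  expect_equal(reactionPropensity(dimer, c(A = 5, B = 0), 2),
               10 / (602.214076 * 2) * 10)
  expect_error(reactionPropensity(AB, c(A = -1, B = 1, C = 0), 1),
               "nonnegative")
})

test_that("doubling the volume halves every second-order propensity exactly", {
  AB <- list(lhs = c(A = 1L, B = 1L), rhs = c(C = 1L), k = 321)
  cn <- c(A = 7, B = 13, C = 2)
  expect_equal(reactionPropensity(AB, cn, 2 * 1.7),
               reactionPropensity(AB, cn, 1.7) / 2, tolerance = 1e-14)
  conv <- list(lhs = c(A = 1L), rhs = c(B = 1L), k = 5)
  expect_equal(reactionPropensity(conv, cn, 2 * 1.7),
               reactionPropensity(conv, cn, 1.7))          # order 1 unaffected
})

test_that("the bundled benchmark model matches its published parameterization", {
  mod <- benchmarkModel()
  sp <- modelSpecies(mod)
  expect_equal(nrow(sp), 10L)
  expect_equal(length(modelReactions(mod)), 8L)  # 4 reversible pairs
  expect_equal(sp$D, seq(100, 10, by = -10))
  expect_equal(unname(initialTotals(mod)), seq(1000, 10000, by = 1000))
  expect_equal(sp$D[sp$name == "J"], 10)
  expect_equal(initialTotals(mod)[["J"]], 10000)
  expect_equal(sum(initialTotals(mod)), 55000)
  ## forward/backward rate constants
  ks <- vapply(modelReactions(mod), function(r) r$k, numeric(1))
  expect_equal(ks, c(1000, 100, 100, 10, 10, 1, 1, 1))
})

test_that("diffusion rate tables follow d_k = D*A/(h*V) and link to neighbor lists", {
  ## all-immobile model: empty table
  m <- twoTetMesh()
  g <- meshGeometry(m)
  im <- reactionModel(data.frame(name = "A", D = 0))
  expect_equal(ncol(diffusionTotals(diffusionRates(m, g, im))), 0L)

  ## isolated tet: d_S,tet = 0
  m1 <- oneTetMesh()
  r1 <- diffusionRates(m1, meshGeometry(m1), freeDiffusionModel(100))
  expect_equal(as.vector(diffusionTotals(r1)), 0)

  ## two tets: equals an independent hand computation from A, h, V
  D <- 100
  rt <- diffusionRates(m, g, freeDiffusionModel(D))
  nb <- meshNeighbors(m)
  f1 <- which(nb[1, ] == 2L)
  hand <- D * g@faceAreas[1, f1] / (g@neighborDist[1, f1] * g@volumes[1])
  expect_equal(unname(diffusionTotals(rt)[1, "X"]), hand, tolerance = 1e-13)
  ## asymmetric in general: tet volumes differ
  f2 <- which(nb[2, ] == 1L)
  hand2 <- D * g@faceAreas[2, f2] / (g@neighborDist[2, f2] * g@volumes[2])
  expect_equal(unname(diffusionTotals(rt)[2, "X"]), hand2, tolerance = 1e-13)

  ## row-link property on a bigger mesh: positive geometry factor exactly at
  ## neighbor faces, zero at boundary faces
  mb <- cuboidMesh(c(2, 2, 2), c(2, 2, 2))
  gb <- meshGeometry(mb)
  rb <- diffusionRates(mb, gb, freeDiffusionModel(50))
  expect_equal(rb@geomFactor > 0, meshNeighbors(mb) != -1L,
               ignore_attr = TRUE)
})

test_that("model JSON round-trips", {
  mod <- benchmarkModel()
  path <- tempfile(fileext = ".json")
  writeModel(mod, path)
  mod2 <- readModel(path)
  expect_equal(modelSpecies(mod2), modelSpecies(mod))
  expect_equal(length(modelReactions(mod2)), length(modelReactions(mod)))
  for (i in seq_along(modelReactions(mod))) {
    a <- modelReactions(mod)[[i]]; b <- modelReactions(mod2)[[i]]
    expect_equal(sort(names(b$lhs)), sort(names(a$lhs)))
    expect_equal(b$k, a$k)
  }
  expect_equal(initialTotals(mod2), initialTotals(mod))
  unlink(path)
})

test_that("model validation rejects malformed inputs", {
  expect_error(reactionModel(data.frame(name = c("A", "A"), D = c(1, 2))),
               "unique")
  expect_error(reactionModel(data.frame(name = "A", D = 1),
                             list(list(lhs = c(A = 3L), rhs = c(A = 1L), k = 1))),
               "order")
  expect_error(reactionModel(data.frame(name = "A", D = 1),
                             list(list(lhs = c(B = 1L), rhs = c(A = 1L), k = 1))),
               "undeclared")
})

test_that("uniform placement preserves totals exactly and follows volume", {
  m <- cuboidMesh(c(10, 10, 100), c(2, 2, 10))
  cnt <- uniformInit(m, c(A = 1000, B = 55))
  expect_equal(colSums(cnt), c(A = 1000, B = 55))
  ## equal-volume tets: counts differ by at most 1
  expect_lte(diff(range(cnt[, "A"])), 1)
})
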