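test_that("the linear grid partitioner bins by barycenter and covers every tet once", {
  mesh <- cuboidMesh(c(10, 10, 100), c(5, 5, 50))
  ## trivial partition
  p1 <- partitionLinear(mesh, c(1, 1, 1))
  expect_equal(partitionRanks(p1), 1L)
  expect_true(all(rankOfTet(p1) == 0L))
  ## the y-z linear scheme for p = 50: parts = (1, 5, 10)
  p50 <- partitionLinear(mesh, c(1, 5, 10))
  expect_equal(partitionRanks(p50), 50L)
  ro <- rankOfTet(p50)
  expect_equal(length(ro), nTets(mesh))
  expect_equal(sort(unique(ro)), 0:49)
  ## each rank holds a contiguous y-z block: check per-rank barycenter boxes
  ## don't overlap in (y, z) bin space
  g <- meshGeometry(mesh)
  b <- tetBarycenters(g)
  ybin <- floor(b[, 2] / 2); zbin <- floor(b[, 3] / 10)
  expect_equal(ro, as.integer(1L * ybin + 5L * zbin))
  ## balanced loading on this uniform mesh
  expect_true(all(tabulate(ro + 1L, 50) == 150L))
})

test_that("partition files round-trip in Metis .epart convention", {
  mesh <- cuboidMesh(c(2, 2, 4), c(1, 1, 4))
  p <- partitionLinear(mesh, c(1, 1, 2))
  path <- tempfile(fileext = ".epart")
  writePartition(p, path)
  p2 <- readPartition(path, nTets = nTets(mesh))
  expect_equal(rankOfTet(p2), rankOfTet(p))
  expect_equal(partitionRanks(p2), partitionRanks(p))
  ## line-count mismatch is an error
  expect_error(readPartition(path, nTets = nTets(mesh) + 1L), "mismatch")
  ## all-zeros file: single-rank partition
  writeLines(rep("0", nTets(mesh)), path)
  expect_equal(partitionRanks(readPartition(path)), 1L)
  unlink(path)
})

test_that("the Metis graph export lists symmetric face adjacency", {
  mesh <- cuboidMesh(c(1, 1, 2), c(1, 1, 2))
  path <- tempfile(fileext = ".graph")
  writeMetisGraph(mesh, path)
  lines <- readLines(path)
  hdr <- scan(text = lines[1], quiet = TRUE)
  expect_equal(hdr[1], nTets(mesh))
  adj <- lapply(lines[-1], function(l) scan(text = l, quiet = TRUE))
  expect_equal(hdr[2], sum(lengths(adj)) / 2)  # each edge listed twice
  for (i in seq_along(adj))
    for (j in adj[[i]])
      expect_true(i %in% adj[[j]])
  unlink(path)
})

test_that("partition topology accessors match brute-force checks", {
  mesh <- cuboidMesh(c(2, 2, 8), c(1, 1, 8))
  p <- partitionLinear(mesh, c(1, 1, 4))
  nb <- meshNeighbors(mesh)
  ro <- rankOfTet(p)
  for (r in 0:3) {
    ## neighbor ranks: symmetric, face-derived
    for (q in neighborRanks(mesh, p, r))
      expect_true(r %in% neighborRanks(mesh, p, q))
    ## boundary tets have a cross-rank face; non-boundary hosted tets do not
    bt <- boundaryTets(mesh, p, r)
    for (t in hostedTets(p, r)) {
      js <- nb[t, nb[t, ] != -1L]
      expect_equal(t %in% bt, any(ro[js] != r))
    }
  }
  ## a rank in the z chain only neighbors adjacent ranks
  expect_equal(neighborRanks(mesh, p, 1L), c(0L, 2L))
})

test_that("rank dependency tables reduce to the serial closure", {
  mesh <- twoTetMesh()
  mod <- reactionModel(data.frame(name = c("A", "B"), D = c(10, 0)),
                       list(list(lhs = c(A = 1L), rhs = c(B = 1L), k = 1)))
  serial <- buildEventDeps(mesh, mod)
  ## single rank: deps(S) empty, deps(R)/deps(D) identical to serial
  p1 <- meshPartition(c(0L, 0L))
  t1 <- buildRankTables(mesh, mod, p1, 0L)
  expect_equal(length(t1$depsS), 0L)
  got <- c(t1$depsR, t1$depsD)
  got <- got[order(as.integer(names(got)))]
  expect_equal(unname(got), serial$deps)

  ## 2-rank split: rank 1's deps(S) for (tet2, A) lists exactly the
  ## rank-1-hosted A-dependent events
  p2 <- meshPartition(c(0L, 1L))
  tA <- buildRankTables(mesh, mod, p2, 0L)
  tB <- buildRankTables(mesh, mod, p2, 1L)
  expect_equal(names(tB$depsS), "2.A")
  ## tet 2 hosts events 3 (rxn, reads A) and 4 (diff A): both depend on A
  expect_equal(sort(tB$depsS[["2.A"]]), c(3L, 4L))
  expect_equal(names(tA$depsS), "1.A")
  expect_equal(sort(tA$depsS[["1.A"]]), c(1L, 2L))

  ## union property: for the cross-rank diffusion tet1 -> tet2 of A, the
  ## source rank's truncated deps(D) plus the destination rank's deps(S)
  ## equal the serial destination-specific closure
  dSerial <- sort(serial$deps[[2]])  # diffusion event of A in tet 1
  dSrc <- sort(tA$depsD[["2"]])
  union <- sort(unique(c(dSrc, tB$depsS[["2.A"]])))
  expect_equal(union, dSerial)
  ## and the pieces are disjoint across ranks (each event hosted once)
  expect_length(intersect(dSrc, tB$depsS[["2.A"]]), 0)
})

test_that("cross-rank deps(S) updates match full recomputation after a remote change", {
  mesh <- cuboidMesh(c(2, 2, 4), c(1, 1, 4))
  pr <- makeBenchmark(0.1, meshCounts = c(1, 1, 4), dims = c(2, 2, 4))
  mod <- problemModel(pr)
  p <- partitionLinear(mesh, c(1, 1, 2))
  rank <- 1L
  tbl <- buildRankTables(mesh, mod, p, rank)
  counts <- initialCounts(pr)
  aBefore <- eventPropensities(pr, counts)
  ## simulate an incoming remote change: +5 of species A in a boundary tet
  bt <- boundaryTets(mesh, p, rank)[1]
  counts2 <- counts
  counts2[bt, "A"] <- counts2[bt, "A"] + 5L
  aAfter <- eventPropensities(pr, counts2)
  changed <- which(aAfter != aBefore)
  ## every changed event must be listed in deps(S) for (bt, A)
  key <- paste0(bt, ".A")
  expect_true(key %in% names(tbl$depsS))
  expect_true(all(changed %in% tbl$depsS[[key]]))
  ## and refreshing only the listed events reproduces the full table
  aIncr <- aBefore
  aIncr[tbl$depsS[[key]]] <- aAfter[tbl$depsS[[key]]]
  expect_equal(aIncr, aAfter)
})
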