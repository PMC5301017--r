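test_that("Kuhn subdivision produces 6 conforming tets per cell with exact volume", {
  m <- cuboidMesh(c(1, 1, 1), c(1, 1, 1))
  expect_equal(nTets(m), 6L)
  g <- meshGeometry(m)
  expect_equal(sum(tetVolumes(g)), 1, tolerance = 1e-12)

  m2 <- cuboidMesh(c(10, 10, 100), c(5, 5, 50))
  expect_equal(nTets(m2), 7500L)  # 6 tets x 1250 cells
  g2 <- meshGeometry(m2)
  expect_equal(sum(tetVolumes(g2)), 10 * 10 * 100, tolerance = 1e-9)
})

test_that("degenerate boxes and bad counts are rejected", {
  expect_error(cuboidMesh(c(1, 1, 0), c(1, 1, 1)), "invalid argument")
  expect_error(cuboidMesh(c(1, 1, 1), c(1, 0, 1)), "invalid argument")
})

test_that("total volume is invariant under mesh refinement", {
  for (cnt in list(c(1, 1, 1), c(2, 2, 2), c(4, 4, 4))) {
    g <- meshGeometry(cuboidMesh(c(3, 2, 5), cnt))
    expect_equal(sum(tetVolumes(g)), 30, tolerance = 1e-9)
  }
})

test_that("neighbor relation is symmetric and interior faces are shared by exactly 2 tets", {
  m <- cuboidMesh(c(2, 2, 3), c(2, 2, 3))
  nb <- meshNeighbors(m)
  ## symmetry, exhaustively
  for (i in seq_len(nTets(m))) {
    for (f in 1:4) {
      j <- nb[i, f]
      if (j != -1L) expect_true(any(nb[j, ] == i))
    }
  }
  ## face-sharing counts via sorted vertex triples
  tt <- meshTets(m)
  omit <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  keys <- unlist(lapply(1:4, function(f)
    apply(tt[, omit[f, ]], 1L, function(v) paste(sort(v), collapse = "."))))
  expect_true(all(table(keys) %in% c(1L, 2L)))
  ## boundary faces of the box: 2 triangles per cell face per side
  expect_equal(sum(nb == -1L), sum(table(keys) == 1L))
})

test_that("geometry matches closed forms", {
  m <- oneTetMesh()
  g <- meshGeometry(m)
  expect_equal(tetVolumes(g), 1 / 6, tolerance = 1e-14)
  expect_equal(tetBarycenters(g)[1, ], c(0.25, 0.25, 0.25))

  ## a shared face has the same area seen from either side
  m2 <- twoTetMesh()
  g2 <- meshGeometry(m2)
  nb <- meshNeighbors(m2)
  f1 <- which(nb[1, ] == 2L)
  f2 <- which(nb[2, ] == 1L)
  expect_equal(g2@faceAreas[1, f1], g2@faceAreas[2, f2], tolerance = 1e-14)
  ## face {2,3,4} is the equilateral triangle with side sqrt(2)
  expect_equal(g2@faceAreas[1, f1], sqrt(3) / 2 * (sqrt(2) / 2)^2 * 2,
               tolerance = 1e-12)
  expect_equal(g2@neighborDist[1, f1],
               sqrt(sum((g2@barycenters[1, ] - g2@barycenters[2, ])^2)))
})

test_that("degenerate tets are reported by name", {
  flat <- tetMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                        c(1, 1, 0)),
                  rbind(1:4))
  expect_s4_class(flat, "TetMesh")
  ## force a degenerate tet past the constructor orientation fix
  degen <- new("TetMesh",
               vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                c(0.5, 0.5, 1e-15)),
               tets = rbind(1:4),
               neighbors = matrix(-1L, 1, 4))
  expect_error(meshGeometry(degen), "mesh-quality error.*tet 1")
})

test_that("mesh round-trips through both file formats", {
  m <- cuboidMesh(c(1, 2, 1), c(1, 2, 1))
  for (fmt in c("text", "msh2")) {
    path <- tempfile(fileext = if (fmt == "msh2") ".msh" else ".txt")
    writeMesh(m, path, format = fmt)
    m2 <- readMesh(path)  # format sniffed
    expect_equal(meshVertices(m2), meshVertices(m))
    expect_equal(meshTets(m2), meshTets(m))
    expect_equal(meshNeighbors(m2), meshNeighbors(m))
    unlink(path)
  }
})

test_that("malformed mesh files raise named parse errors", {
  ## native file with a 5-index tet row
  path <- tempfile()
  writeLines(c("1 4", "0 0 0", "1 0 0", "0 1 0", "0 0 1", "0 1 2 3 3"), path)
  expect_error(readMesh(path, format = "text"), "line 6")
  unlink(path)
  ## MSH v2 with only triangles
  path <- tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", "3", "1 0 0 0", "2 1 0 0", "3 0 1 0", "$EndNodes",
               "$Elements", "1", "1 2 2 0 0 1 2 3", "$EndElements"), path)
  expect_error(readMesh(path), "no tetrahedral")
  unlink(path)
})

test_that("connectivity is rebuilt, not trusted from file", {
  m <- cuboidMesh(c(1, 1, 2), c(1, 1, 2))
  path <- tempfile()
  writeMesh(m, path)  # the native format stores no connectivity at all
  m2 <- readMesh(path)
  expect_equal(meshNeighbors(m2), meshNeighbors(m))
  unlink(path)
})
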