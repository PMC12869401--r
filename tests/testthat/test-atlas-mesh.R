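test_that("icosphere subdivision gives closed meshes with the expected counts", {
  expect_error(buildIcosphere(-1), "non-negative")
  for (lev in 0:3) {
    m <- buildIcosphere(lev)
    nv <- 10 * 4^lev + 2
    expect_equal(nVertices(m), nv)
    expect_equal(nrow(meshFaces(m)), 20 * 4^lev)
    # Euler characteristic V - E + F = 2 for a closed sphere mesh
    ne <- sum(lengths(meshAdjacency(m))) / 2
    expect_equal(nv - ne + nrow(meshFaces(m)), 2)
    # unit sphere
    expect_equal(max(abs(rowSums(meshVertices(m)^2) - 1)), 0, tolerance = 1e-12)
  }
})

test_that("vertex ordering nests across subdivision levels", {
  m1 <- buildIcosphere(1)
  m2 <- buildIcosphere(2)
  expect_equal(meshVertices(m2)[seq_len(nVertices(m1)), ], meshVertices(m1),
               tolerance = 1e-12)
  h <- tiny_hierarchy(0:2)
  for (i in 1:2) {
    coarse <- levelMesh(h, i); fine <- levelMesh(h, i + 1)
    for (hemi in 1:2) {
      ci <- which(hemiId(coarse) == hemi)
      fi <- which(hemiId(fine) == hemi)
      expect_equal(meshVertices(fine)[fi[seq_along(ci)], ],
                   meshVertices(coarse)[ci, ], tolerance = 1e-12)
    }
  }
})

test_that("adjacency is symmetric, deduplicated, and matches a brute-force scan", {
  m <- buildIcosphere(1)
  adj <- meshAdjacency(m)
  # degree profile of an ico1 sphere: 12 original vertices keep degree 5,
  # 30 edge midpoints have degree 6
  expect_equal(sort(as.integer(table(lengths(adj)))), c(12L, 30L))
  expect_equal(lengths(meshAdjacency(buildIcosphere(0))), rep(5L, 12))
  # brute force from faces
  f <- meshFaces(m)
  for (v in sample(nVertices(m), 8)) {
    rows <- which(f[, 1] == v | f[, 2] == v | f[, 3] == v)
    nb <- sort(setdiff(unique(as.integer(f[rows, ])), v))
    expect_identical(sort(adj[[v]]), nb)
    expect_false(v %in% adj[[v]])
  }
  # symmetry
  for (v in seq_along(adj)) for (u in adj[[v]]) expect_true(v %in% adj[[u]])
})

test_that("single-triangle mesh adjacency gives each vertex two neighbours", {
  tri <- geromorph:::.newMesh(diag(3), matrix(1:3, 1), "left")
  expect_equal(lengths(meshAdjacency(tri)), rep(2L, 3))
})

test_that("khopNeighbors matches breadth-first search", {
  m0 <- buildIcosphere(0)
  expect_length(khopNeighbors(m0, 1, 1), 5)
  # the icosahedron graph has diameter 3: 5 neighbours, 5 at distance two,
  # and one antipodal vertex at distance three
  expect_length(khopNeighbors(m0, 1, 2), 10)
  expect_length(khopNeighbors(m0, 1, 3), 11)
  expect_error(khopNeighbors(m0, 99, 1), "valid vertex")
  # path graph 1-2-3 encoded as two degenerate triangles is not a manifold;
  # use the adjacency-list entry point instead
  adj <- list(2L, c(1L, 3L), 2L)
  expect_identical(khopNeighbors(adj, 1, 2), c(2L, 3L))
  # BFS oracle on ico1
  m1 <- buildIcosphere(1)
  adj1 <- meshAdjacency(m1)
  for (v in c(1, 17, 42)) {
    for (k in 1:3) {
      # plain loop BFS
      dist <- rep(Inf, nVertices(m1)); dist[v] <- 0
      for (step in 1:k) for (u in which(is.finite(dist) & dist <= step - 1))
        for (w in adj1[[u]]) dist[w] <- min(dist[w], step)
      expect_identical(khopNeighbors(m1, v, k),
                       sort(which(is.finite(dist) & dist > 0)))
    }
  }
})

test_that("hemisphere concatenation offsets indices and keeps components separate", {
  lh <- buildIcosphere(1, "left"); rh <- buildIcosphere(1, "right")
  j <- concatenateHemispheres(lh, rh)
  expect_equal(nVertices(j), 84)
  expect_equal(nrow(meshFaces(j)), 2 * nrow(meshFaces(lh)))
  expect_equal(sort(unique(graphComponents(j))), 1:2)
  # adjacency of the left block is unchanged by concatenation
  expect_identical(meshAdjacency(j)[seq_len(nVertices(lh))], meshAdjacency(lh))
  # reference-scale count at ico4
  j4 <- concatenateHemispheres(buildIcosphere(4, "left"),
                               buildIcosphere(4, "right"))
  expect_equal(nVertices(j4), 5124)
})

test_that("hierarchy construction validates levels and builds wall masks", {
  expect_error(buildAtlasHierarchy(c(2, 1)), "strictly increasing")
  h <- tiny_hierarchy(0:2)
  expect_equal(vertexCounts(h), c(24L, 84L, 324L))
  expect_equal(nLevels(h), 3)
  for (i in 1:3) {
    expect_equal(sort(unique(graphComponents(levelMesh(h, i)))), 1:2)
    expect_length(medialWall(h, i), vertexCounts(h)[i])
  }
  # wall cap: every wall vertex is within the angular radius of its pole
  mesh <- levelMesh(h, "finest")
  wall <- medialWall(h)
  v <- meshVertices(mesh)
  v[, 1] <- v[, 1] + ifelse(hemiId(mesh) == 1, 2, -2)
  ang <- acos(pmin(1, pmax(-1, v[, 1] * ifelse(hemiId(mesh) == 1, 1, -1))))
  expect_true(all(ang[wall] <= 0.25))
  expect_true(all(ang[!wall] > 0.25))
})

test_that("FreeSurfer surface and morph files round-trip", {
  m <- buildIcosphere(2)
  surf <- tempfile(fileext = ".surf")
  writeFreeSurferGeometry(m, surf)
  m2 <- readFreeSurferGeometry(surf)
  expect_equal(meshVertices(m2), meshVertices(m), tolerance = 1e-7)  # float32
  expect_identical(meshFaces(m2), meshFaces(m))

  curv <- tempfile(fileext = ".curv")
  x <- rnorm(nVertices(m))
  writeFreeSurferMorph(x, curv, nFaces = nrow(meshFaces(m)))
  expect_equal(readFreeSurferMorph(curv), x, tolerance = 1e-7)
  expect_equal(readFreeSurferMorph(curv, expectedVertices = 162), x,
               tolerance = 1e-7)
  expect_error(readFreeSurferMorph(curv, expectedVertices = 163), "mismatch")
  writeFreeSurferMorph(rep(1, 162), curv)
  expect_equal(readFreeSurferMorph(curv), rep(1, 162))
})

test_that("FreeSurfer readers reject bad magics and truncation with offsets", {
  bad <- tempfile()
  writeBin(as.raw(c(0xFF, 0xFF, 0xF0, 0x00)), bad)
  expect_error(readFreeSurferGeometry(bad), "magic.*offset 0")
  expect_error(readFreeSurferMorph(bad), "magic.*offset 0")
  # truncated surface: header only
  con <- file(bad, "wb")
  writeBin(as.raw(c(0xFF, 0xFF, 0xFE)), con)
  writeBin(charToRaw("x"), con); writeBin(as.raw(c(10, 10)), con)
  writeBin(c(100L, 50L), con, size = 4, endian = "big")
  close(con)
  expect_error(readFreeSurferGeometry(bad), "truncated")
})

test_that("annot files round-trip labels and region names", {
  labels <- rep(c(101L, 202L, 303L), times = c(5, 7, 4))
  p <- tempfile(fileext = ".annot")
  writeFreeSurferAnnot(labels, p, regionNames = c("front", "mid", "back"))
  r <- readFreeSurferAnnot(p)
  expect_identical(r$labels, labels)
  expect_identical(r$table$name, c("front", "mid", "back"))
  expect_identical(r$table$code, c(101L, 202L, 303L))
})

test_that("array containers round-trip named arrays", {
  arrs <- list(vertices = matrix(rnorm(12), 4), faces = matrix(1:6, 2),
               medial_wall = c(TRUE, FALSE))
  p <- tempfile(fileext = ".rds")
  writeArrayContainer(arrs, p)
  expect_identical(readArrayContainer(p), arrs)
})
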