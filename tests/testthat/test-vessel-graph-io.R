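test_that("VesselGraph validity rejects malformed graphs", {
  expect_error(VesselGraph(1:2, rbind(c(0, 0), c(1, 0)), c(1, -1),
                           rbind(c(1, 2))), "radii")
  expect_error(VesselGraph(c(1L, 1L), rbind(c(0, 0), c(1, 0)), c(1, 1),
                           NULL), "unique")
  expect_error(VesselGraph(1:2, rbind(c(0, 0), c(1, 0)), c(1, 1),
                           rbind(c(1, 1))), "loop")
  expect_error(VesselGraph(1:2, rbind(c(0, 0), c(1, 0)), c(1, 1),
                           rbind(c(1, 3))), "existing")
})

test_that("degree counts incident edges and sums to twice the edge count", {
  g <- pathGraph(3)
  expect_identical(as.integer(nodeDegree(g)), c(1L, 2L, 1L))
  s <- starGraph(3)
  expect_identical(unname(nodeDegree(s, 1)), 3L)
  expect_error(nodeDegree(g, 99), "unknown")
  iso <- VesselGraph(1:2, rbind(c(0, 0), c(5, 5)), c(1, 1), NULL)
  expect_identical(unname(nodeDegree(iso, 1)), 0L)
  for (gg in list(g, s, yGraph()))
    expect_equal(sum(nodeDegree(gg)), 2 * nEdges(gg))
})

test_that("extent is recomputed from node positions", {
  g <- VesselGraph(1:3, rbind(c(0, 0), c(3, 1), c(1, 5)), rep(1, 3),
                   rbind(c(1, 2), c(2, 3)))
  expect_equal(graphExtent(g), c(x = 3, y = 5))
})

test_that("SWC reader handles roots, chains and malformed records", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines("1 2 0 0 0 1.0 -1", f)
  g <- readSWC(f, dropIsolated = FALSE)
  expect_equal(nNodes(g), 1)
  expect_equal(nEdges(g), 0)

  writeLines(c("# comment", "1 2 0 0 0 1.0 -1", "2 2 1 0 0 1.0 1",
               "3 2 2 0 0 1.0 2"), f)
  g <- readSWC(f)
  expect_equal(nNodes(g), 3)
  expect_equal(nEdges(g), 2)  # one edge per record with parent != -1
  expect_identical(sort(as.integer(nodeDegree(g))), c(1L, 1L, 2L))
  expect_equal(graphDim(g), 2L)  # constant z auto-detected as planar

  writeLines(c("1 2 0 0 0 1.0 -1", "2 2 1 0 0 0 1"), f)
  expect_error(readSWC(f), "line 2.*radius")
  writeLines(c("1 2 0 0 0 1 -1", "1 2 1 0 0 1 1"), f)
  expect_error(readSWC(f), "line 2.*duplicate")
  writeLines(c("1 2 0 0 0 1 -1", "2 2 1 0 0 1 9"), f)
  expect_error(readSWC(f), "line 2.*unknown")
})

test_that("SWC reader detects 3D input and drops tiny components", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 2 0 0 0 1 -1", "2 2 1 0 1 1 1", "3 2 2 0 2 1 2"), f)
  expect_equal(graphDim(readSWC(f)), 3L)
  # an isolated pair is tracing noise: pruned with a warning
  writeLines(c("1 2 0 0 0 1 -1", "2 2 1 0 0 1 1", "3 2 2 0 0 1 2",
               "10 2 9 9 0 1 -1", "11 2 9 8 0 1 10"), f)
  expect_warning(g <- readSWC(f), "isolated")
  expect_equal(sort(nodeIds(g)), 1:3)
})

test_that("JSON graph dialect round-trips arbitrary graphs", {
  f <- withr::local_tempfile(fileext = ".json")
  # cyclic graph: representable in JSON, rejected by SWC
  g <- VesselGraph(c(4L, 1L, 7L), rbind(c(0, 0), c(1, 0), c(0.5, 1)),
                   c(1, 2, 0.5), rbind(c(4, 1), c(1, 7), c(7, 4)))
  writeGraphJSON(g, f)
  g2 <- readGraphJSON(f)
  expect_equal(sort(nodeIds(g2)), sort(nodeIds(g)))
  expect_equal(nodeCoords(g2)[as.character(nodeIds(g)), ],
               nodeCoords(g)[as.character(nodeIds(g)), ])
  expect_equal(nodeRadii(g2)[as.character(nodeIds(g))],
               nodeRadii(g)[as.character(nodeIds(g))])
  expect_equal(graphEdges(g2), graphEdges(g))
  expect_error(writeSWC(g, withr::local_tempfile()), "cycle")

  empty <- VesselGraph(integer(0), matrix(numeric(0), ncol = 2),
                       numeric(0), NULL)
  writeGraphJSON(empty, f)
  expect_equal(nNodes(readGraphJSON(f)), 0)
})

test_that("JSON schema violations are reported with their JSON path", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"dim": 2, "nodes": [{"id": 1, "pos": [0, 0], "radius": 1}],
              "edges": [[1, 1]]}', f)
  expect_error(readGraphJSON(f), "edges\\[1\\].*self loop")
  writeLines('{"dim": 2, "nodes": [{"id": 1, "pos": [0, 0]}], "edges": []}',
             f)
  expect_error(readGraphJSON(f), "nodes\\[1\\].*radius")
  writeLines('{"nodes": [], "edges": []}', f)
  expect_error(readGraphJSON(f), "dim")
})

test_that("SWC and JSON readers agree on equivalent tree inputs", {
  tr <- generateTree(treeConfig(seed = 5, depth = 3L))$graph
  fs <- withr::local_tempfile(fileext = ".swc")
  fj <- withr::local_tempfile(fileext = ".json")
  writeSWC(tr, fs)
  writeGraphJSON(tr, fj)
  a <- readSWC(fs)
  b <- readGraphJSON(fj)
  expect_equal(sort(nodeIds(a)), sort(nodeIds(b)))
  expect_equal(graphEdges(a), graphEdges(b))
  ia <- as.character(nodeIds(a))
  expect_equal(nodeCoords(a)[ia, ], nodeCoords(b)[ia, ], tolerance = 1e-9)
  expect_equal(nodeRadii(a)[ia], nodeRadii(b)[ia], tolerance = 1e-9)
})

test_that("writeSWC round-trips a tree through parent pointers", {
  tr <- generateTree(treeConfig(seed = 9, depth = 3L))$graph
  f <- withr::local_tempfile(fileext = ".swc")
  writeSWC(tr, f)
  back <- readSWC(f)
  expect_equal(sort(nodeIds(back)), sort(nodeIds(tr)))
  expect_equal(graphEdges(back), graphEdges(tr))
})
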