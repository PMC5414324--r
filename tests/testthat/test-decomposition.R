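test_that("forward direction follows the CCW-from-+x convention", {
  g <- VesselGraph(1:4, rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, -1)),
                   rep(1, 4), rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(forwardDirection(g, 1, 2), 0)
  expect_equal(forwardDirection(g, 1, 3), 90)
  expect_equal(forwardDirection(g, 1, 4), 225)
  g3 <- VesselGraph(1:2, rbind(c(0, 0, 0), c(0, 0, 2)), c(1, 1),
                    rbind(c(1, 2)))
  expect_equal(forwardDirection(g3, 1, 2), c(0, 0, 1))
  gz <- VesselGraph(1:2, rbind(c(0, 0), c(0, 0)), c(1, 1), rbind(c(1, 2)))
  expect_error(forwardDirection(gz, 1, 2), "zero-length")
})

test_that("tortuosity is the arc-chord ratio", {
  expect_equal(pathTortuosity(cbind(0:3, 0)), 1.0)
  expect_equal(pathTortuosity(rbind(c(0, 0), c(1, 0), c(1, 1))), 2 / sqrt(2))
  # dense samples of a semicircle approach pi / 2
  t <- seq(0, pi, length.out = 400)
  expect_equal(pathTortuosity(cbind(cos(t), sin(t))), pi / 2,
               tolerance = 1e-4)
  expect_error(pathTortuosity(rbind(c(0, 0), c(1, 1), c(0, 0))),
               "coincident")
})

test_that("a star decomposes into edge-disjoint salient-to-leaf arms", {
  # plus-shaped graph: salient center, 4 two-node arms
  g <- VesselGraph(1:9,
    rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1), c(0, 2), c(-1, 0), c(-2, 0),
          c(0, -1), c(0, -2)),
    rep(1, 9),
    rbind(c(1, 2), c(2, 3), c(1, 4), c(4, 5), c(1, 6), c(6, 7), c(1, 8),
          c(8, 9)))
  d <- decomposeGraph(g, 1L)
  expect_length(d$branches, 4)
  expect_true(all(vapply(d$branches, branchKind, "") == "salient-leaf"))
  allNodes <- unlist(lapply(d$branches, branchNodes))
  expect_false(anyDuplicated(allNodes) > 0)
  expect_equal(nrow(d$residual), 0)
  # every branch is anchored at the salient point but excludes it
  expect_true(all(vapply(d$branches, branchAnchor, 0L) == 1L))
  expect_false(any(allNodes == 1L))
})

test_that("two salient nodes joined by one path give one branch", {
  g <- pathGraph(5)
  d <- decomposeGraph(g, c(1L, 5L))
  k1 <- Filter(function(b) branchKind(b) == "salient-salient", d$branches)
  expect_length(k1, 1)
  expect_equal(branchNodes(k1[[1]]), 2:5)  # terminal salient included
  expect_equal(nrow(d$residual), 0)
})

test_that("branch edges and residual edges partition the graph", {
  tr <- generateTree(treeConfig(seed = 13))$graph
  sc <- computeNSI(tr)
  sal <- salientCandidates(tr, sc)$id
  d <- decomposeGraph(tr, sal)
  claimed <- do.call(rbind, lapply(d$branches, function(b) {
    path <- c(branchAnchor(b), branchNodes(b))
    cbind(pmin(path[-length(path)], path[-1]),
          pmax(path[-length(path)], path[-1]))
  }))
  res <- d$residual
  all <- rbind(claimed, cbind(pmin(res[, 1], res[, 2]),
                              pmax(res[, 1], res[, 2])))
  key <- paste(all[, 1], all[, 2])
  expect_false(anyDuplicated(key) > 0)                 # pairwise disjoint
  ge <- graphEdges(tr)
  expect_setequal(key, paste(ge[, 1], ge[, 2]))        # cover all edges
  # no branch interior contains a salient node
  for (b in d$branches) {
    interior <- branchNodes(b)
    if (branchKind(b) == "salient-salient")
      interior <- interior[-length(interior)]
    expect_false(any(interior %in% sal))
  }
})

test_that("salient-to-salient anchoring follows the anchor rank", {
  g <- pathGraph(4)
  rk <- c(`1` = 1, `4` = 2)
  d <- decomposeGraph(g, c(1L, 4L), rk)
  expect_equal(branchAnchor(d$branches[[1]]), 4L)
  rk2 <- c(`1` = 2, `4` = 1)
  d2 <- decomposeGraph(g, c(1L, 4L), rk2)
  expect_equal(branchAnchor(d2$branches[[1]]), 1L)
})

test_that("branch features are rigid-invariant; direction is equivariant", {
  tr <- generateTree(treeConfig(seed = 17, depth = 3L))$graph
  sc <- computeNSI(tr)
  sal <- salientCandidates(tr, sc)$id
  d0 <- decomposeGraph(tr, sal)
  rot <- 0.6
  moved <- transformGraph(tr, function(m) rigid2d(m, rot, c(5, 5)))
  d1 <- decomposeGraph(moved, sal)
  expect_equal(length(d0$branches), length(d1$branches))
  for (k in seq_along(d0$branches)) {
    a <- d0$branches[[k]]; b <- d1$branches[[k]]
    expect_equal(b@tortuosity, a@tortuosity, tolerance = 1e-12)
    expect_equal(b@sumRadius, a@sumRadius, tolerance = 1e-12)
    expect_equal((b@direction - a@direction) %% 360, rot * 180 / pi,
                 tolerance = 1e-9)
  }
})

test_that("branch table export mirrors the feature columns", {
  d <- decomposeGraph(yGraph(), 1L)
  f <- withr::local_tempfile(fileext = ".tsv")
  exportBranchTable(d$branches, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_setequal(names(tab),
                  c("branchId", "kind", "anchor", "terminal", "nNodes",
                    "tortuosity", "sumRadius", "forwardDirection"))
  expect_equal(nrow(tab), length(d$branches))
  expect_true(all(tab$tortuosity >= 1))
})
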