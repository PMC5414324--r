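mkMatch <- function(leading, deltaV, base, clamped = FALSE) {
  data.frame(i = 1L, leadingNode = leading, deltaV = deltaV,
             baseNode = base, clamped = clamped)
}

test_that("interpolation walks deltaV of the way from the base node", {
  g <- pathGraph(4)  # nodes at x = 0..3
  b <- decomposeGraph(g, 1L)$branches[[1]]  # members 2,3,4 at x = 1,2,3
  expect_equal(interpolatePosition(b, mkMatch(1L, 0, 1L), g), c(1, 0))
  expect_equal(interpolatePosition(b, mkMatch(1L, 0.25, 1L), g),
               c(1.25, 0))
  # base at the succeeding node: walk backwards from it
  expect_equal(interpolatePosition(b, mkMatch(1L, 0.25, 2L), g),
               c(1.75, 0))
  # deltaV = 0.5: midpoint regardless of the base end
  expect_equal(interpolatePosition(b, mkMatch(1L, 0.5, 1L), g),
               interpolatePosition(b, mkMatch(1L, 0.5, 2L), g))
  # clamped matches sit exactly on the base node
  expect_equal(interpolatePosition(b, mkMatch(3L, 0, 3L, TRUE), g),
               c(3, 0))
})

test_that("identity registration fuses with zero deviation everywhere", {
  g <- generateTree(treeConfig(seed = 41))$graph
  reg <- registerVessels(g, g)
  fn <- fusedNodes(reg@fused)
  dev <- as.matrix(fn[, c("dx", "dy")])
  expect_equal(max(abs(dev)), 0)
  expect_true(all(fn$provenance %in% c("matched", "shifted")))
  # congruent with the reference: every fused node sits on its own position
  expect_equal(as.matrix(fn[order(fn$sensedId), c("x", "y")]),
               unname(nodeCoords(g)[as.character(sort(nodeIds(g))), ]),
               ignore_attr = TRUE)
  # and every correspondence has zero voltage difference
  expect_true(all(vapply(reg@nodeMatches,
                         function(m) all(m$deltaV == 0), logical(1))))
})

test_that("every sensed node appears exactly once in the fused output", {
  p <- simulatePair(treeConfig(seed = 43),
                    deformConfig(seed = 44, spurCount = 3, deleteCount = 1))
  reg <- registerVessels(p$reference, p$sensed)
  fn <- fusedNodes(reg@fused)
  expect_setequal(fn$sensedId, nodeIds(p$sensed))
  expect_false(anyDuplicated(fn$sensedId) > 0)
})

test_that("shifted structure moves rigidly by its anchor's deviation", {
  p <- simulatePair(treeConfig(seed = 45),
                    deformConfig(seed = 46, spurCount = 2, deleteCount = 0))
  reg <- registerVessels(p$reference, p$sensed)
  fn <- fusedNodes(reg@fused)
  shifted <- fn[fn$provenance == "shifted", ]
  expect_gt(nrow(shifted), 0)  # the interference spurs have no partner
  sen <- reg@sensed
  adj <- vesselreg:::.adjacency(sen)
  # each shifted node's offset equals the deviation of some placed neighbor
  devTab <- fn
  rownames(devTab) <- as.character(devTab$sensedId)
  for (id in shifted$sensedId) {
    nb <- unlist(adj[as.character(id)])
    ok <- any(vapply(nb, function(b) {
      isTRUE(all.equal(unlist(devTab[b, c("dx", "dy")]),
                       unlist(devTab[as.character(id), c("dx", "dy")]),
                       tolerance = 1e-9))
    }, logical(1)))
    expect_true(ok)
  }
})

test_that("registration error summarizes per-node distances", {
  g <- generateTree(treeConfig(seed = 47))$graph
  reg <- registerVessels(g, g)
  truth <- data.frame(sensedId = nodeIds(g), refId = nodeIds(g))
  err <- registrationError(reg@fused, truth)
  expect_equal(err$mean, 0)
  expect_equal(err$fracWithin, 1)
  # uniform offset: mean error equals the offset norm
  fused2 <- reg@fused
  cn <- c("x", "y")
  fused2@nodes[, cn] <- fused2@nodes[, cn] +
    rep(c(3, 4), each = nrow(fused2@nodes))
  err2 <- registrationError(fused2, truth)
  expect_equal(err2$mean, 5, tolerance = 1e-12)
  expect_equal(err2$max, 5, tolerance = 1e-12)
  # scoring a subset only scores that subset
  sub <- truth[1:10, ]
  err3 <- registrationError(fused2, sub)
  expect_equal(err3$n, 10)
  # ids absent from the fused graph warn and are dropped
  extra <- rbind(truth, data.frame(sensedId = 9999L, refId = 1L))
  expect_warning(err4 <- registrationError(reg@fused, extra), "absent")
  expect_equal(err4$n, nNodes(g))
})

test_that("fused graphs export with provenance tags", {
  g <- generateTree(treeConfig(seed = 49, depth = 3L))$graph
  reg <- registerVessels(g, g)
  f <- withr::local_tempfile(fileext = ".json")
  writeFusedJSON(reg@fused, f)
  x <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(length(x$nodes), nNodes(g))
  expect_true(all(vapply(x$nodes, function(n) n$provenance, "")
                  %in% c("matched", "shifted", "unmatched")))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  exportCorrespondence(reg@fused, f2)
  tab <- read.table(f2, header = TRUE, sep = "\t")
  expect_setequal(tab$sensedId, nodeIds(g))
})
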