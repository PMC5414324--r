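mkCircuit <- function(r, th, E) {
  new("CircuitBranch", branchId = 1L, E = E,
      Z = complex(real = r * cos(th), imaginary = r * sin(th)),
      theta = th, radius = r)
}

test_that("node impedance splits the radius by the deviation angle", {
  expect_equal(nodeImpedance(1, 0), 1 + 0i)
  expect_equal(nodeImpedance(2, pi / 2), 2i)
  expect_equal(nodeImpedance(2, pi / 3), complex(real = 1,
                                                 imaginary = sqrt(3)),
               tolerance = 1e-12)
  expect_error(nodeImpedance(0, 0), "radius")
  expect_error(nodeImpedance(1, -0.1), "theta")
  # modulus identity |Z| = r
  r <- runif(20, 0.1, 5); th <- runif(20, 0, pi)
  expect_equal(Mod(nodeImpedance(r, th)), r, tolerance = 1e-12)
})

test_that("deviation angles compare local forward to the whole branch", {
  g <- VesselGraph(1:4, rbind(c(-1, 0), c(0, 0), c(1, 0), c(1, 1)),
                   rep(1, 4), rbind(c(1, 2), c(2, 3), c(3, 4)))
  d <- decomposeGraph(g, 1L)
  b <- d$branches[[1]]           # members 2,3,4; whole vector (0,0)->(1,1)
  th <- deviationAngles(b, g)
  expect_equal(th[1], pi / 4, tolerance = 1e-12)   # local (1,0) vs (1,1)
  expect_equal(th[2], pi / 4, tolerance = 1e-12)   # local (0,1) vs (1,1)
  expect_equal(th[3], pi / 4, tolerance = 1e-12)   # reuses previous segment
  # straight branches deviate nowhere
  gs <- pathGraph(6)
  bs <- decomposeGraph(gs, 1L)$branches[[1]]
  expect_equal(deviationAngles(bs, gs), rep(0, 5), tolerance = 1e-12)
})

test_that("branch circuits carry NSI sources and radius-modulus impedances", {
  g <- pathGraph(4, radii = c(1, 2, 0.5, 1.5))
  sc <- computeNSI(g)
  b <- decomposeGraph(g, 1L)$branches[[1]]
  circ <- branchToCircuit(b, g, sc)
  expect_equal(circ@E,
               unname(nsiValues(sc)[as.character(branchNodes(b))]))
  expect_equal(sum(Mod(circ@Z)), b@sumRadius, tolerance = 1e-12)
  expect_equal(circ@Z, complex(real = c(2, 0.5, 1.5)), tolerance = 1e-12)
})

test_that("single-source loop solves match brute-force mesh analysis", {
  circ <- mkCircuit(rep(1, 3), rep(0, 3), rep(1, 3))
  expect_equal(solveSingleSource(circ, 1), c(1, 2, 1) / c(1, 3, 3) + 0i,
               tolerance = 1e-12)
  expect_equal(solveSingleSource(circ, 3), c(0, -1 / 3, 1 / 3) + 0i,
               tolerance = 1e-12)
  zero <- mkCircuit(rep(1, 3), rep(0, 3), c(1, 0, 1))
  expect_equal(solveSingleSource(zero, 2), rep(0 + 0i, 3))
})

test_that("closed form agrees with the generic nodal-analysis oracle", {
  set.seed(401)
  worst <- 0
  for (k in 1:40) {
    n <- sample(2:30, 1)
    circ <- randomCircuit(n)
    for (j in sample(n, min(n, 3))) {
      a <- solveSingleSource(circ, j)
      b <- solveCircuitMNA(circ, j)
      worst <- max(worst, max(Mod(a - b)) / max(Mod(b), 1e-12))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("superposition holds for the loop netlist", {
  set.seed(402)
  for (k in 1:10) {
    circ <- randomCircuit(sample(2:15, 1))
    n <- length(circ@Z)
    together <- solveCircuitMNA(circ)
    summed <- Reduce(`+`, lapply(seq_len(n),
                                 function(j) solveCircuitMNA(circ, j)))
    expect_lt(max(Mod(together - summed)) / max(Mod(together)), 1e-12)
  }
})

test_that("integrated voltage sequence averages the excitation history", {
  one <- mkCircuit(2, 0, 3)
  expect_equal(voltages(integratedVoltageSequence(one)), 3 + 0i)
  circ <- mkCircuit(rep(1, 3), rep(0, 3), rep(1, 3))
  expect_equal(voltages(integratedVoltageSequence(circ)),
               c(1, 2 / 3, 1 / 3) + 0i, tolerance = 1e-12)
  # complex loop: Z = [1, i, 1]; second node is 1 - 1/(2 + i)
  mixed <- new("CircuitBranch", branchId = 1L, E = rep(1, 3),
               Z = c(1 + 0i, 1i, 1 + 0i), theta = c(0, pi / 2, 0),
               radius = rep(1, 3))
  expect_equal(voltages(integratedVoltageSequence(mixed))[2], 0.6 + 0.2i,
               tolerance = 1e-12)
  # closed form and averaged MNA single-source solves agree
  set.seed(403)
  rc <- randomCircuit(12)
  expect_equal(voltages(integratedVoltageSequence(rc)),
               voltages(integratedVoltageSequence(rc, solver = "mna")),
               tolerance = 1e-9)
})

test_that("the first node reproduces its source exactly", {
  set.seed(404)
  circ <- randomCircuit(10)
  v <- voltages(integratedVoltageSequence(circ))
  expect_identical(Re(v[1]), circ@E[1])
  # perturbing any radius leaves node 1 unchanged
  for (k in c(1, 5, 10)) {
    r2 <- circ@radius; r2[k] <- r2[k] * 3
    circ2 <- mkCircuit(r2, circ@theta, circ@E)
    expect_equal(voltages(integratedVoltageSequence(circ2))[1], v[1])
  }
})

test_that("straight constant-source branches have decreasing magnitude", {
  circ <- mkCircuit(runif(20, 0.5, 3), rep(0, 20), rep(4, 20))
  m <- voltageMagnitude(integratedVoltageSequence(circ))
  expect_true(all(diff(m) < 0))
})

test_that("an interior radius error leaves the branch start untouched and
           grows towards the end", {
  n <- 34
  base <- mkCircuit(rep(2.2, n), rep(0, n), rep(5, n))
  hurt <- mkCircuit(c(rep(2.2, 9), 0.01, rep(2.2, n - 10)), rep(0, n),
                    rep(5, n))
  m0 <- voltageMagnitude(integratedVoltageSequence(base))
  m1 <- voltageMagnitude(integratedVoltageSequence(hurt))
  rel <- abs(m1 - m0) / m0
  expect_equal(rel[1], 0)
  expect_true(all(diff(rel) >= -1e-12))
  expect_gte(rel[n], max(rel) - 1e-12)
})

test_that("diagnostics localize thickness steps and turning points", {
  # thickness halved at the midpoint of a straight branch
  n <- 20
  step <- mkCircuit(c(rep(2, 10), rep(1, 10)), rep(0, n), rep(1, n))
  d <- sequenceDiagnostics(integratedVoltageSequence(step))
  expect_true(abs(d$peakMagGradientChange - 10) <= 1)
  expect_equal(d$magGradient, diff(Mod(voltages(
    integratedVoltageSequence(step)))))
  # 90-degree kink at node 10 of an L-shaped branch
  pos <- rbind(cbind(0:9, 0), cbind(9, 1:10))
  nn <- nrow(pos)
  g <- VesselGraph(seq_len(nn), pos, rep(1, nn),
                   cbind(seq_len(nn - 1), 2:nn))
  b <- decomposeGraph(g, 1L)$branches[[1]]
  circ <- branchToCircuit(b, g, computeNSI(g))
  dk <- sequenceDiagnostics(integratedVoltageSequence(circ))
  kink <- 9  # node 10 of the graph is member 9 of the branch
  expect_true(abs(dk$peakArgGradient - kink) <= 1)
  # constant sequence: zero gradients
  flat <- new("VoltageSequence", branchId = 1L, voltage = rep(2 + 0i, 5))
  df <- sequenceDiagnostics(flat)
  expect_equal(df$magGradient, rep(0, 4))
  expect_equal(df$argGradient, rep(0, 4))
  expect_error(sequenceDiagnostics(new("VoltageSequence", branchId = 1L,
                                       voltage = 1 + 0i)), "at least 2")
})

test_that("near-singular loops are rejected with the branch named", {
  g <- VesselGraph(1:3, rbind(c(0, 0), c(1, 0), c(0, 0.0001)), rep(1, 3),
                   rbind(c(1, 2), c(2, 3)))
  d <- decomposeGraph(g, 1L)
  expect_error(new("CircuitBranch", branchId = 1L, E = c(1, 1),
                   Z = c(1 + 0i, -1 + 1e-12i), theta = c(0, pi),
                   radius = c(1, 1)), "singular")
})

test_that("voltage sequences export with magnitude and argument columns", {
  circ <- mkCircuit(rep(1, 4), rep(0, 4), 4:1)
  seq <- integratedVoltageSequence(circ)
  f <- withr::local_tempfile(fileext = ".tsv")
  exportVoltageSequence(seq, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(tab$magnitude, voltageMagnitude(seq), tolerance = 1e-9)
  expect_equal(nrow(tab), 4)
})
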