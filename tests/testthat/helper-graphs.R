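# in-code fixtures shared across test files

# path graph 1-2-...-n along +x, unit spacing
pathGraph <- function(n, radii = rep(1, n), dim = 2L) {
  coords <- cbind(seq_len(n) - 1, matrix(0, n, dim - 1))
  edges <- if (n > 1) cbind(seq_len(n - 1), 2:n) else NULL
  VesselGraph(seq_len(n), coords, radii, edges, dim = dim)
}

# k-leaf star: center id 1 at origin, leaves on the unit circle
starGraph <- function(k, radii = rep(1, k + 1)) {
  ang <- 2 * pi * (seq_len(k) - 1) / k
  coords <- rbind(c(0, 0), cbind(cos(ang), sin(ang)))
  VesselGraph(seq_len(k + 1), coords, radii, cbind(1, 1 + seq_len(k)))
}

# Y: salient center 4 with three 2-node arms
yGraph <- function() {
  coords <- rbind(c(0, 0), c(0, 1), c(-1, -1), c(-2, -2), c(1, -1), c(2, -2),
                  c(0, 2))
  VesselGraph(1:7, coords, rep(1, 7),
              rbind(c(1, 2), c(1, 3), c(3, 4), c(1, 5), c(5, 6), c(2, 7)))
}

# random solvable circuit branch (rejection-samples away near-singular loops)
randomCircuit <- function(n, thetaMax = pi) {
  repeat {
    r <- stats::runif(n, 0.1, 5)
    th <- stats::runif(n, 0, thetaMax)
    E <- stats::runif(n, 0, 10)
    Z <- complex(real = r * cos(th), imaginary = r * sin(th))
    if (Mod(sum(Z)) > 1e-6 * sum(Mod(Z)))
      return(new("CircuitBranch", branchId = 1L, E = E, Z = Z,
                 theta = th, radius = r))
  }
}

# rigid 2D motion: rotation by angle (radians) then translation
rigid2d <- function(coords, angle, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  t(R %*% t(coords)) + rep(shift, each = nrow(coords))
}

# apply a coordinate transform to a VesselGraph
transformGraph <- function(g, f, radiusScale = 1) {
  VesselGraph(nodeIds(g), f(nodeCoords(g)), radiusScale * g@radius,
              graphEdges(g), dim = graphDim(g))
}
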