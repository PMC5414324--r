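#' @include decomposition.R
NULL

#' Node impedance from radius and deviation angle
#'
#' Converts a node to its series resistance/inductance pair at the fixed
#' angular frequency of 1 rad/s: \code{R = r cos(theta)} and
#' \code{i w L = i r sin(theta)}, i.e. \code{Z = r exp(i theta)}.  The
#' modulus of the impedance is exactly the radius; the split between real
#' and imaginary part carries the local curvature.
#'
#' @param r positive radius (vectorized).
#' @param theta deviation angle in radians, in [0, pi] (vectorized).
#' @return complex impedance(s).
#' @examples
#' nodeImpedance(2, pi / 2)  # pure inductance 2i
#' @export
nodeImpedance <- function(r, theta) {
  if (any(r <= 0)) stop("radius must be > 0")
  if (any(theta < 0 | theta > pi)) stop("theta must lie in [0, pi]")
  complex(real = r * cos(theta), imaginary = r * sin(theta))
}

#' Deviation angles of branch nodes
#'
#' For node k of a branch, the unsigned angle in [0, pi] between the local
#' forward vector (node k to node k+1; the last node reuses the previous
#' segment) and the whole-branch vector (first node to last node).  A
#' straight branch has all-zero deviation; a single-node branch has
#' deviation 0 by convention.
#'
#' @param branch a [Branch-class].
#' @param graph the [VesselGraph-class] it came from.
#' @return numeric vector of angles in radians, one per branch node.
#' @export
deviationAngles <- function(branch, graph) {
  ids <- branchNodes(branch)
  n <- length(ids)
  if (n == 1) return(0)
  p <- .posOf(graph, ids)
  whole <- p[n, ] - p[1, ]
  nw <- sqrt(sum(whole^2))
  if (nw == 0) stop("coincident branch endpoints")
  vapply(seq_len(n), function(k) {
    v <- if (k < n) p[k + 1, ] - p[k, ] else p[n, ] - p[n - 1, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("coincident consecutive branch nodes")
    acos(min(1, max(-1, sum(v * whole) / (nv * nw))))
  }, numeric(1))
}

#' Convert a branch to its circuit image
#'
#' Each branch node k becomes a voltage source of magnitude \code{E_k} equal
#' to its NSI value (phase 0) in series with the impedance
#' \code{Z_k = nodeImpedance(r_k, theta_k)}; the element order follows the
#' branch orientation from its anchoring salient point.
#'
#' @param branch a [Branch-class].
#' @param graph the source [VesselGraph-class].
#' @param nsi [NsiScores-class] of the graph.
#' @return a [CircuitBranch-class].
#' @export
branchToCircuit <- function(branch, graph, nsi) {
  ids <- branchNodes(branch)
  r <- as.numeric(nodeRadii(graph)[as.character(ids)])
  th <- deviationAngles(branch, graph)
  Z <- nodeImpedance(r, th)
  if (Mod(sum(Z)) <= 1e-9 * sum(Mod(Z)))
    stop(sprintf("branch %d: near-singular loop impedance", branch@id))
  new("CircuitBranch", branchId = branch@id,
      E = as.numeric(nsiValues(nsi)[as.character(ids)]),
      Z = Z, theta = th, radius = r)
}

setMethod("show", "CircuitBranch", function(object) {
  cat(sprintf("CircuitBranch (branch %d): %d segments, |Z_tot| = %.4g\n",
              object@branchId, length(object@Z), Mod(sum(object@Z))))
})

#' Solve the loop for a single active source (closed form)
#'
#' The default series-loop topology chains the n segments (source then
#' impedance) through ground; the probe of node k sits between its source
#' and impedance.  With only source j active, the loop current is
#' \code{E_j / Z_tot} and the probe voltage at node k is
#' \deqn{v_k^{(j)} = E_j\,([j \le k] - S_{k-1}/Z_{tot})}
#' with partial sums \code{S_k = Z_1 + ... + Z_k}, \code{S_0 = 0}.
#'
#' @param circuit a [CircuitBranch-class].
#' @param j index of the active source.
#' @return complex probe voltage per node.
#' @seealso [solveCircuitMNA()] for the independent generic nodal solve of
#'   the same netlist.
#' @export
solveSingleSource <- function(circuit, j) {
  n <- length(circuit@Z)
  stopifnot(j >= 1, j <= n)
  Ztot <- sum(circuit@Z)
  if (Mod(Ztot) <= 1e-9 * sum(Mod(circuit@Z)))
    stop("near-singular loop impedance")
  S <- c(0, cumsum(circuit@Z))[seq_len(n)]       # S_{k-1}
  circuit@E[j] * ((j <= seq_len(n)) - S / Ztot)
}

#' Generic complex nodal-analysis solve of the series-loop netlist
#'
#' Independent oracle for [solveSingleSource()]: assembles the modified
#' nodal-analysis system of the same netlist (junctions, probe nodes and
#' source currents as unknowns; inactive sources become shorts) and solves
#' it with a dense complex linear solve.  Supports any subset of sources
#' active simultaneously, which makes the superposition property directly
#' testable.
#'
#' @param circuit a [CircuitBranch-class].
#' @param active indices of active sources (default: all).
#' @return complex probe voltage per node.
#' @export
solveCircuitMNA <- function(circuit, active = seq_along(circuit@Z)) {
  n <- length(circuit@Z)
  Z <- circuit@Z
  Esrc <- numeric(n)
  Esrc[active] <- circuit@E[active]
  # unknowns: J_1..J_{n-1}, P_1..P_n, I_1..I_n  (J_0 = J_n = ground)
  nu <- (n - 1) + 2 * n
  A <- matrix(0 + 0i, nu, nu)
  b <- complex(nu)
  Jv <- function(k) if (k >= 1 && k <= n - 1) k else 0L   # 0 => ground
  Pv <- function(k) (n - 1) + k
  Iv <- function(k) (n - 1) + n + k
  row <- 0L
  for (k in seq_len(n)) {       # KCL at probe P_k: I_k - (P_k - J_k)/Z_k = 0
    row <- row + 1L
    A[row, Iv(k)] <- 1
    A[row, Pv(k)] <- A[row, Pv(k)] - 1 / Z[k]
    if (Jv(k) > 0) A[row, Jv(k)] <- A[row, Jv(k)] + 1 / Z[k]
  }
  for (k in seq_len(n - 1)) {   # KCL at junction J_k
    row <- row + 1L
    A[row, Pv(k)] <- A[row, Pv(k)] + 1 / Z[k]
    A[row, Jv(k)] <- A[row, Jv(k)] - 1 / Z[k]
    A[row, Iv(k + 1)] <- -1
  }
  for (k in seq_len(n)) {       # source k: P_k - J_{k-1} = E_k (0 if short)
    row <- row + 1L
    A[row, Pv(k)] <- 1
    if (Jv(k - 1) > 0) A[row, Jv(k - 1)] <- -1
    b[row] <- Esrc[k]
  }
  x <- solve(A, b)
  x[(n - 1) + seq_len(n)]
}

#' Integrated voltage sequence of a branch circuit
#'
#' Sources are excited one at a time in branch order; the voltage response
#' of node k is the average of its steady-state phasor responses to
#' excitations 1 through k inclusive, which damps instabilities from any
#' single erroneous node.  Under the series-loop topology this reduces to
#' the closed form
#' \deqn{\tilde V_k = \mathrm{mean}(E_1..E_k)\,(1 - S_{k-1}/Z_{tot}),}
#' so the first node reproduces its source exactly.
#'
#' @param circuit a [CircuitBranch-class].
#' @param solver "closed_form" (default) or "mna" to average the generic
#'   nodal single-source solves instead.
#' @return a [VoltageSequence-class].
#' @export
integratedVoltageSequence <- function(circuit,
                                      solver = c("closed_form", "mna")) {
  solver <- match.arg(solver)
  n <- length(circuit@Z)
  v <- if (solver == "closed_form") {
    Ztot <- sum(circuit@Z)
    S <- c(0, cumsum(circuit@Z))[seq_len(n)]
    (cumsum(circuit@E) / seq_len(n)) * (1 - S / Ztot)
  } else {
    resp <- vapply(seq_len(n), function(j) solveCircuitMNA(circuit, j),
                   complex(n))
    resp <- matrix(resp, n, n)   # [node, source]
    vapply(seq_len(n), function(k) mean(resp[k, seq_len(k)]), complex(1))
  }
  new("VoltageSequence", branchId = circuit@branchId, voltage = v)
}

#' @rdname voltage-accessors
setMethod("voltages", "VoltageSequence", function(x) x@voltage)
#' @rdname voltage-accessors
setMethod("voltageMagnitude", "VoltageSequence", function(x) Mod(x@voltage))
#' @rdname voltage-accessors
setMethod("voltageArgument", "VoltageSequence", function(x) {
  as.numeric(signal::unwrap(Arg(x@voltage)))
})
setMethod("length", "VoltageSequence", function(x) length(x@voltage))

setMethod("show", "VoltageSequence", function(object) {
  cat(sprintf("VoltageSequence (branch %d): %d nodes, |V| in [%.4g, %.4g]\n",
              object@branchId, length(object@voltage),
              min(Mod(object@voltage)), max(Mod(object@voltage))))
})

#' Gradient diagnostics of an integrated voltage sequence
#'
#' First differences of the magnitude and of the unwrapped argument, plus
#' the change of the magnitude gradient.  A fast-descending magnitude
#' gradient marks a trend towards a thinner vessel area, so the peak
#' magnitude-gradient change localizes a thickness step; an evident change
#' in the argument marks a large turning point in the branch.
#'
#' @param seq a [VoltageSequence-class] with at least 2 nodes.
#' @return list with \code{magGradient}, \code{argGradient},
#'   \code{magGradientChange} (second difference of magnitude) and peak
#'   locations \code{peakMagGradient}, \code{peakMagGradientChange},
#'   \code{peakArgGradient} (indices of the largest absolute entry; the
#'   gradient at index k spans nodes k and k+1).
#' @export
sequenceDiagnostics <- function(seq) {
  n <- length(voltages(seq))
  if (n < 2) stop("diagnostics need at least 2 nodes")
  mg <- diff(voltageMagnitude(seq))
  ag <- diff(voltageArgument(seq))
  mgc <- if (n >= 3) diff(mg) else numeric(0)
  list(magGradient = mg, argGradient = ag, magGradientChange = mgc,
       peakMagGradient = which.max(abs(mg)),
       peakMagGradientChange = if (length(mgc)) which.max(abs(mgc))
                               else NA_integer_,
       peakArgGradient = which.max(abs(ag)))
}

#' Export a voltage sequence as TSV
#'
#' Columns: node index, real and imaginary part, magnitude and argument,
#' ready for plotting magnitude/argument profiles of a branch.
#'
#' @param seq a [VoltageSequence-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
exportVoltageSequence <- function(seq, path) {
  v <- voltages(seq)
  utils::write.table(
    data.frame(node = seq_along(v), re = Re(v), im = Im(v),
               magnitude = Mod(v), argument = voltageArgument(seq)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
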