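#' @import methods
NULL

#' Spatial vessel centerline graph
#'
#' A \code{VesselGraph} holds the skeleton of a vascular structure: nodes with
#' 2D or 3D coordinates (continuous image/physical units, never voxel indices)
#' and a positive radius, connected by undirected edges along vessel paths.
#' It is the substrate of the registration pipeline.
#'
#' @slot ids integer vector of unique node identifiers.
#' @slot coords numeric matrix, one row per node, \code{dim} columns.
#' @slot radius numeric vector of positive node radii (the node weight).
#' @slot edges two-column integer matrix of undirected edges, each row an
#'   unordered id pair stored as (small, large); no self loops, no duplicates.
#' @slot dim integer, 2 or 3.
#'
#' @seealso [VesselGraph()], [readSWC()], [readGraphJSON()]
#' @export
setClass("VesselGraph",
  representation(ids = "integer", coords = "matrix", radius = "numeric",
                 edges = "matrix", dim = "integer"))

setValidity("VesselGraph", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) msg <- c(msg, "node ids must be unique")
  if (!(object@dim %in% c(2L, 3L))) msg <- c(msg, "dim must be 2 or 3")
  if (nrow(object@coords) != n || ncol(object@coords) != object@dim)
    msg <- c(msg, "coords must be an n x dim matrix")
  if (length(object@radius) != n) msg <- c(msg, "radius length must equal node count")
  if (n > 0 && any(!is.finite(object@radius) | object@radius <= 0))
    msg <- c(msg, "all radii must be finite and > 0")
  e <- object@edges
  if (ncol(e) != 2) msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0) {
    if (any(e[, 1] == e[, 2])) msg <- c(msg, "self loops are not allowed")
    if (!all(e %in% object@ids)) msg <- c(msg, "edge endpoints must be existing node ids")
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Per-node Network Structure Index scores
#'
#' Container for the saliency score of every node of one [VesselGraph], with
#' the neighborhood parameters that produced it.  The score of node v is
#' \deqn{NSI(v) = \sum_{u: d(v,u) \le h} r(u)\, deg(u)\, \lambda^{d(v,u)}}
#' where d is the hop distance, r the radius and deg the degree; an isolated
#' node scores 0.
#'
#' @slot scores named numeric vector, names are node ids.
#' @slot h integer hop horizon.
#' @slot lambda decay per hop, in (0, 1].
#' @seealso [computeNSI()]
#' @export
setClass("NsiScores",
  representation(scores = "numeric", h = "integer", lambda = "numeric"))

setValidity("NsiScores", function(object) {
  msg <- character()
  if (is.null(names(object@scores)) && length(object@scores) > 0)
    msg <- c(msg, "scores must be named by node id")
  if (any(object@scores < 0)) msg <- c(msg, "NSI scores are non-negative")
  if (object@lambda <= 0 || object@lambda > 1) msg <- c(msg, "lambda must be in (0, 1]")
  if (object@h < 0) msg <- c(msg, "h must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A salient-free branch of a decomposed vessel graph
#'
#' An ordered node path anchored at a structurally salient point.  The anchor
#' is not a member of the branch; the first member is adjacent to it.  A
#' salient-to-salient branch ends at (and includes) its terminal salient
#' node; a salient-to-leaf branch ends at a degree-1 node.  The three
#' matching features are stored alongside.
#'
#' @slot id integer branch identifier within its decomposition.
#' @slot nodes ordered integer vector of member node ids.
#' @slot kind "salient-salient" or "salient-leaf".
#' @slot anchor id of the anchoring salient node (not a member).
#' @slot terminal id of the far end (terminal salient node or leaf).
#' @slot direction forward direction at the anchor: in 2D a single CCW angle
#'   in degrees from +x in [0, 360); in 3D a unit vector.
#' @slot sumRadius sum of member radii (a vessel-volume proxy).
#' @slot tortuosity arc length over chord length of the anchor..terminal
#'   polyline; >= 1, with equality iff collinear.
#' @export
setClass("Branch",
  representation(id = "integer", nodes = "integer", kind = "character",
                 anchor = "integer", terminal = "integer",
                 direction = "numeric", sumRadius = "numeric",
                 tortuosity = "numeric"))

setValidity("Branch", function(object) {
  msg <- character()
  if (length(object@nodes) < 1) msg <- c(msg, "a branch has at least one node")
  if (!(object@kind %in% c("salient-salient", "salient-leaf")))
    msg <- c(msg, "kind must be salient-salient or salient-leaf")
  if (object@anchor %in% object@nodes) msg <- c(msg, "anchor must not be a branch member")
  if (length(object@tortuosity) && is.finite(object@tortuosity) &&
      object@tortuosity < 1 - 1e-12)
    msg <- c(msg, "tortuosity must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Electrical image of a branch
#'
#' Each branch node k becomes a series circuit segment: a real voltage source
#' of magnitude \code{E[k]} (the node's NSI, phase 0) followed by a complex
#' impedance \code{Z[k] = r_k cos(theta_k) + i r_k sin(theta_k)}, where r_k is
#' the node radius and theta_k the deviation of the node's local forward
#' direction from the whole-branch direction.  Segments are chained into a
#' single loop closed through ground, so |Z[k]| = r_k and the loop is
#' solvable whenever |sum(Z)| is not negligible against sum(|Z|).
#'
#' @slot branchId integer id of the source branch.
#' @slot E numeric source magnitudes (NSI values), phase 0.
#' @slot Z complex impedances.
#' @slot theta numeric deviation angles in radians, in [0, pi].
#' @slot radius numeric node radii.
#' @seealso [branchToCircuit()], [integratedVoltageSequence()]
#' @export
setClass("CircuitBranch",
  representation(branchId = "integer", E = "numeric", Z = "complex",
                 theta = "numeric", radius = "numeric"))

setValidity("CircuitBranch", function(object) {
  msg <- character()
  n <- length(object@Z)
  if (length(object@E) != n || length(object@theta) != n ||
      length(object@radius) != n)
    msg <- c(msg, "E, Z, theta and radius must have equal length")
  if (n > 0) {
    if (any(object@radius <= 0)) msg <- c(msg, "radii must be > 0")
    if (any(object@theta < -1e-12 | object@theta > pi + 1e-12))
      msg <- c(msg, "theta must lie in [0, pi]")
    if (max(abs(Mod(object@Z) - object@radius)) > 1e-9 * max(object@radius))
      msg <- c(msg, "|Z_k| must equal r_k")
    if (Mod(sum(object@Z)) <= 1e-9 * sum(Mod(object@Z)))
      msg <- c(msg, "near-singular loop: |sum(Z)| <= 1e-9 * sum(|Z|)")
  }
  if (length(msg)) msg else TRUE
})

#' Integrated voltage sequence of a circuit branch
#'
#' The complex voltage response per branch node: node k stores the average of
#' its steady-state phasor responses to the excitations of sources 1..k.
#' Magnitude and argument views are available through accessors and drive the
#' node-matching stage and the thickness/turning-point diagnostics.
#'
#' @slot branchId integer id of the source branch.
#' @slot voltage complex vector, one entry per branch node.
#' @seealso [integratedVoltageSequence()], [sequenceDiagnostics()]
#' @export
setClass("VoltageSequence",
  representation(branchId = "integer", voltage = "complex"))

#' Fused registration output
#'
#' The reference graph passes through unchanged; every sensed node receives
#' exactly one fused position together with its deviation vector
#' (fused minus original sensed position) and a provenance tag:
#' \describe{
#'   \item{matched}{placed on a reference branch by its voltage match (or a
#'     salient-pair correspondence).}
#'   \item{shifted}{member of an unmatched sensed structure translated
#'     rigidly by the deviation of its matched anchor node.}
#'   \item{unmatched}{no matched anchor reachable; carried over untransformed
#'     and flagged.}
#' }
#'
#' @slot reference the reference [VesselGraph], unchanged.
#' @slot sensed the original sensed [VesselGraph].
#' @slot nodes data.frame over all sensed nodes: \code{sensedId},
#'   fused coordinates \code{x,y(,z)}, deviations \code{dx,dy(,dz)},
#'   \code{provenance}, logical \code{flagged}.
#' @seealso [fuseGraphs()], [registrationError()]
#' @export
setClass("FusedGraph",
  representation(reference = "VesselGraph", sensed = "VesselGraph",
                 nodes = "data.frame"))

setValidity("FusedGraph", function(object) {
  msg <- character()
  ids <- object@nodes$sensedId
  if (length(ids) != length(object@sensed@ids) || anyDuplicated(ids) ||
      !all(sort(ids) == sort(object@sensed@ids)))
    msg <- c(msg, "fused output must contain every sensed node exactly once")
  if (!all(object@nodes$provenance %in% c("matched", "shifted", "unmatched")))
    msg <- c(msg, "unknown provenance tag")
  if (length(msg)) msg else TRUE
})

#' Full result of a registration run
#'
#' Bundle of every intermediate of the pipeline run by [registerVessels()]:
#' NSI scores, salient pairs, branch decompositions, branch pairing,
#' per-branch node matches, and the fused graph, plus the effective
#' parameters.
#'
#' @slot reference,sensed the input graphs (after small-component pruning).
#' @slot nsiRef,nsiSensed [NsiScores] of each side.
#' @slot salientPairs data.frame of matched structurally salient points.
#' @slot refBranches,sensedBranches lists of [Branch].
#' @slot refResidual,sensedResidual residual edge matrices not claimed by any
#'   branch.
#' @slot branchPairs data.frame of branch correspondences with the deciding
#'   criterion and feature differences.
#' @slot nodeMatches named list (by ref branch id) of per-node match tables.
#' @slot fused the [FusedGraph].
#' @slot parameters list of effective run parameters.
#' @export
setClass("VesselRegistration",
  representation(reference = "VesselGraph", sensed = "VesselGraph",
                 nsiRef = "NsiScores", nsiSensed = "NsiScores",
                 salientPairs = "data.frame",
                 refBranches = "list", sensedBranches = "list",
                 refResidual = "matrix", sensedResidual = "matrix",
                 branchPairs = "data.frame",
                 nodeMatches = "list", fused = "FusedGraph",
                 parameters = "list"))
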