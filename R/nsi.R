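#' @include vessel-graph.R
NULL

#' Network Structure Index
#'
#' Per-node structural saliency score combining the node weight (radius), its
#' connectivity (degree) and the decayed contribution of its neighborhood:
#' \deqn{NSI(v) = \sum_{u:\, d(v,u) \le h} r(u)\, deg(u)\, \lambda^{d(v,u)}}
#' with hop distance d (so \code{u = v} contributes at decay 1).  The score
#' is purely topological/radiometric: it is invariant under rigid motion of
#' the coordinates, scales linearly with a global radius scale, and depends
#' only on the h-hop ball around each node, which makes it robust to distant
#' structure going missing (unlike betweenness centrality).
#'
#' The formula is exposed as a swappable strategy through \code{scoreFun};
#' the default implements the decayed radius-degree sum above.
#'
#' @param graph a [VesselGraph-class].
#' @param h hop horizon (default 2).
#' @param lambda per-hop decay in (0, 1] (default 0.5).
#' @param scoreFun optional replacement strategy: a
#'   \code{function(radius, degree, hopdist, lambda)} returning one score
#'   from the vectors over a node's h-ball.
#' @return an [NsiScores-class] object.
#' @examples
#' g <- VesselGraph(1:3, cbind(0:2, 0), c(1, 1, 1), rbind(c(1, 2), c(2, 3)))
#' nsiValues(computeNSI(g, h = 1))  # middle node scores 2 + 0.5 * 2 = 3
#' @export
computeNSI <- function(graph, h = 2L, lambda = 0.5, scoreFun = NULL) {
  stopifnot(h >= 0, lambda > 0, lambda <= 1)
  n <- nNodes(graph)
  deg <- as.numeric(nodeDegree(graph))
  r <- graph@radius
  if (is.null(scoreFun))
    scoreFun <- function(radius, degree, hopdist, lambda)
      sum(radius * degree * lambda^hopdist)
  scores <- numeric(n)
  if (n > 0) {
    D <- igraph::distances(.asIgraph(graph))  # hop counts, order of @ids
    ord <- match(as.character(graph@ids), colnames(D))
    D <- D[ord, ord, drop = FALSE]
    for (i in seq_len(n)) {
      inBall <- which(D[i, ] <= h)
      scores[i] <- scoreFun(r[inBall], deg[inBall], D[i, inBall], lambda)
    }
  }
  new("NsiScores", scores = stats::setNames(scores, as.character(graph@ids)),
      h = as.integer(h), lambda = lambda)
}

#' @rdname computeNSI
#' @param x an [NsiScores-class] object.
#' @return \code{nsiValues}: the named numeric score vector.
setMethod("nsiValues", "NsiScores", function(x) x@scores)

setMethod("show", "NsiScores", function(object) {
  cat(sprintf("NsiScores: %d nodes (h = %d, lambda = %g)\n",
              length(object@scores), object@h, object@lambda))
  if (length(object@scores))
    cat(sprintf("  range: [%.4g, %.4g]\n",
                min(object@scores), max(object@scores)))
})

#' Structurally salient candidates
#'
#' All nodes of degree at least three, ordered by descending NSI (ties by
#' ascending id).  These are the bifurcation-type anchor candidates for
#' decomposition and matching.
#'
#' @param graph a [VesselGraph-class].
#' @param scores [NsiScores-class] computed on \code{graph}.
#' @return data.frame with columns \code{id}, \code{nsi}, \code{degree};
#'   zero rows when the graph has no degree >= 3 node.
#' @export
salientCandidates <- function(graph, scores) {
  deg <- nodeDegree(graph)
  keep <- which(as.integer(deg) >= 3L)
  ids <- graph@ids[keep]
  nsi <- as.numeric(nsiValues(scores)[as.character(ids)])
  ord <- order(-nsi, ids)
  data.frame(id = ids[ord], nsi = nsi[ord], degree = as.integer(deg[keep])[ord])
}

#' Match structurally salient points between two graphs
#'
#' A reference candidate qualifies when its NSI is the maximum among
#' reference candidates within Euclidean distance rho of itself (a spatial
#' local maximum; this suppresses lower-NSI bifurcations spawned by small
#' interference branches).  Each qualifying candidate is paired with the
#' highest-NSI sensed candidate lying within rho of the reference node's
#' position.  The pairing is one-to-one; conflicts are resolved greedily in
#' descending reference-NSI order.  rho is \code{rhoFrac} times the largest
#' bounding-box edge of the reference graph (the "5\% of image size"
#' neighborhood, adjustable for vessel size and density).
#'
#' @param ref,sensed the two [VesselGraph-class] objects.
#' @param refScores,sensedScores their [NsiScores-class].
#' @param rhoFrac neighborhood radius as a fraction of the reference extent
#'   (default 0.05).
#' @return data.frame with columns \code{refId}, \code{sensedId},
#'   \code{refNsi}, \code{sensedNsi}, \code{distance}; zero rows (with a
#'   warning) when either side has no candidate, in which case registration
#'   cannot proceed.
#' @export
matchSalientPoints <- function(ref, sensed, refScores, sensedScores,
                               rhoFrac = 0.05) {
  rho <- rhoFrac * max(graphExtent(ref))
  refCand <- salientCandidates(ref, refScores)
  senCand <- salientCandidates(sensed, sensedScores)
  empty <- data.frame(refId = integer(0), sensedId = integer(0),
                      refNsi = numeric(0), sensedNsi = numeric(0),
                      distance = numeric(0))
  if (nrow(refCand) == 0 || nrow(senCand) == 0) {
    warning("no structurally salient candidates on at least one side; ",
            "registration cannot proceed")
    return(empty)
  }
  refPos <- .posOf(ref, refCand$id)
  senPos <- .posOf(sensed, senCand$id)
  # local-maximum test among reference candidates
  isLocalMax <- vapply(seq_len(nrow(refCand)), function(i) {
    d <- sqrt(colSums((t(refPos) - refPos[i, ])^2))
    !any(d <= rho & refCand$nsi > refCand$nsi[i])
  }, logical(1))
  usedSensed <- logical(nrow(senCand))
  out <- empty
  for (i in which(isLocalMax)) {         # already in descending-NSI order
    d <- sqrt(colSums((t(senPos) - refPos[i, ])^2))
    inRange <- which(d <= rho & !usedSensed)
    if (!length(inRange)) next
    j <- inRange[order(-senCand$nsi[inRange], senCand$id[inRange])][1]
    usedSensed[j] <- TRUE
    out <- rbind(out, data.frame(refId = refCand$id[i],
                                 sensedId = senCand$id[j],
                                 refNsi = refCand$nsi[i],
                                 sensedNsi = senCand$nsi[j],
                                 distance = d[j]))
  }
  rownames(out) <- NULL
  out
}

#' Export salient pairs as TSV
#'
#' @param pairs result of [matchSalientPoints()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
exportSalientPairs <- function(pairs, path) {
  utils::write.table(
    pairs[, c("refId", "sensedId", "refNsi", "sensedNsi", "distance")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
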