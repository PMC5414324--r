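#' @include node-matching.R
NULL

#' Interpolated fused position of a matched node
#'
#' The voltage difference of a node match is read as a fractional offset in
#' distance: the fused position lies \code{deltaV} of the way from the base
#' node towards the other bracketing node along the straight segment between
#' them.  Clamped matches sit exactly on their base node.
#'
#' @param refBranch the reference [Branch-class].
#' @param match one row of a [matchNodes()] table (list or one-row
#'   data.frame with \code{leadingNode}, \code{deltaV}, \code{baseNode},
#'   \code{clamped}).
#' @param graph the reference [VesselGraph-class].
#' @return numeric position vector.
#' @export
interpolatePosition <- function(refBranch, match, graph) {
  ids <- branchNodes(refBranch)
  j <- match$leadingNode
  base <- match$baseNode
  other <- if (base == j) j + 1L else j
  pBase <- as.numeric(.posOf(graph, ids[base]))
  if (isTRUE(match$clamped) || other > length(ids) || match$deltaV == 0)
    return(pBase)
  pOther <- as.numeric(.posOf(graph, ids[other]))
  pBase + match$deltaV * (pOther - pBase)
}

#' Fuse the sensed graph onto the reference frame
#'
#' Matched sensed nodes are placed at their interpolated positions on the
#' reference branches (salient pairs sit exactly on their reference
#' partners) and their deviation vectors (fused minus original sensed
#' position) are recorded.  Every remaining sensed structure that touches a
#' placed node -- unmatched branches, interference spurs, residual edges --
#' is translated rigidly by the deviation of its anchoring placed node (the
#' end with the smallest deviation magnitude when several qualify, a
#' least-motion choice).  Sensed components with no placed anchor are
#' carried over untransformed and flagged.  The reference graph passes
#' through unchanged.
#'
#' @param ref,sensed the two [VesselGraph-class] objects.
#' @param salientPairs data.frame from [matchSalientPoints()].
#' @param refBranches,sensedBranches branch lists from [decomposeGraph()].
#' @param branchPairs pairing data.frame from [matchBranches()].
#' @param nodeMatches named list (by ref branch id) of [matchNodes()]
#'   tables.
#' @return a [FusedGraph-class].
#' @export
fuseGraphs <- function(ref, sensed, salientPairs, refBranches,
                       sensedBranches, branchPairs, nodeMatches) {
  dim <- graphDim(ref)
  sIds <- nodeIds(sensed)
  fused <- matrix(NA_real_, length(sIds), dim)
  rownames(fused) <- as.character(sIds)
  prov <- stats::setNames(rep("unmatched", length(sIds)), as.character(sIds))
  flagged <- stats::setNames(rep(FALSE, length(sIds)), as.character(sIds))

  place <- function(id, pos) {
    key <- as.character(id)
    if (is.na(fused[key, 1])) {
      fused[key, ] <<- pos
      prov[key] <<- "matched"
    }
  }

  # salient pairs sit exactly on their reference partners
  for (k in seq_len(nrow(salientPairs)))
    place(salientPairs$sensedId[k],
          as.numeric(.posOf(ref, salientPairs$refId[k])))

  refById <- stats::setNames(refBranches,
    vapply(refBranches, function(b) as.character(b@id), character(1)))
  senById <- stats::setNames(sensedBranches,
    vapply(sensedBranches, function(b) as.character(b@id), character(1)))

  for (k in seq_len(nrow(branchPairs))) {
    rb <- refById[[as.character(branchPairs$refBranch[k])]]
    sb <- senById[[as.character(branchPairs$sensedBranch[k])]]
    m <- nodeMatches[[as.character(branchPairs$refBranch[k])]]
    if (is.null(m)) next
    sNodes <- branchNodes(sb)
    for (i in seq_len(nrow(m)))
      place(sNodes[m$i[i]], interpolatePosition(rb, m[i, ], ref))
    flagged[as.character(sNodes[m$i[m$clamped]])] <- TRUE
  }

  # rigid shift of unplaced structure anchored at placed nodes
  sPos <- nodeCoords(sensed)
  placed <- !is.na(fused[, 1])
  dev <- fused
  dev[placed, ] <- fused[placed, , drop = FALSE] - sPos[placed, , drop = FALSE]
  if (any(!placed)) {
    adj <- .adjacency(sensed)
    sub <- igraph::induced_subgraph(.asIgraph(sensed),
                                    as.character(sIds[!placed]))
    comp <- igraph::components(sub)
    for (ci in seq_len(comp$no)) {
      members <- names(comp$membership)[comp$membership == ci]
      # anchor: placed neighbor of the component with least deviation
      nb <- unique(unlist(adj[members]))
      nb <- nb[!is.na(fused[nb, 1])]
      if (length(nb)) {
        mag <- sqrt(rowSums(dev[nb, , drop = FALSE]^2))
        anchor <- nb[order(mag, as.integer(nb))][1]
        off <- dev[anchor, ]
        fused[members, ] <- sPos[members, , drop = FALSE] +
          rep(off, each = length(members))
        dev[members, ] <- rep(off, each = length(members))
        prov[members] <- "shifted"
      } else {
        fused[members, ] <- sPos[members, , drop = FALSE]
        dev[members, ] <- 0
        prov[members] <- "unmatched"
        flagged[members] <- TRUE
      }
    }
  }

  nodes <- data.frame(sensedId = sIds)
  cn <- c("x", "y", "z")[seq_len(dim)]
  for (a in seq_len(dim)) nodes[[cn[a]]] <- fused[, a]
  dn <- c("dx", "dy", "dz")[seq_len(dim)]
  for (a in seq_len(dim)) nodes[[dn[a]]] <- dev[, a]
  nodes$provenance <- unname(prov)
  nodes$flagged <- unname(flagged)
  new("FusedGraph", reference = ref, sensed = sensed, nodes = nodes)
}

# adjacency as named list: id -> character neighbor ids
.adjacency <- function(graph) {
  ids <- as.character(graph@ids)
  adj <- stats::setNames(vector("list", length(ids)), ids)
  e <- graph@edges
  for (k in seq_len(nrow(e))) {
    a <- as.character(e[k, 1]); b <- as.character(e[k, 2])
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' @rdname fuseGraphs
#' @param x a [FusedGraph-class].
#' @return \code{fusedNodes}: the per-node fusion table (positions,
#'   deviations, provenance).
setMethod("fusedNodes", "FusedGraph", function(x) x@nodes)

setMethod("show", "FusedGraph", function(object) {
  tab <- table(object@nodes$provenance)
  cat(sprintf("FusedGraph: %d reference nodes, %d sensed nodes\n",
              nNodes(object@reference), nNodes(object@sensed)))
  cat("  sensed provenance:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

#' Fused graph as a VesselGraph in the reference frame
#'
#' @param fused a [FusedGraph-class].
#' @return a [VesselGraph-class] of the sensed topology at fused positions.
#' @export
fusedVesselGraph <- function(fused) {
  s <- fused@sensed
  cn <- c("x", "y", "z")[seq_len(graphDim(s))]
  coords <- as.matrix(fused@nodes[, cn])
  VesselGraph(fused@nodes$sensedId, coords,
              s@radius[.rowOf(s, fused@nodes$sensedId)], s@edges,
              dim = graphDim(s))
}

#' Export the correspondence table as TSV
#'
#' @param fused a [FusedGraph-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
exportCorrespondence <- function(fused, path) {
  utils::write.table(fusedNodes(fused), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a fused graph in the JSON graph dialect with provenance
#'
#' @param fused a [FusedGraph-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFusedJSON <- function(fused, path) {
  g <- fusedVesselGraph(fused)
  prov <- stats::setNames(fused@nodes$provenance,
                          as.character(fused@nodes$sensedId))
  ord <- order(g@ids)
  nodes <- lapply(ord, function(i) {
    list(id = g@ids[i], pos = as.numeric(g@coords[i, ]),
         radius = g@radius[i], provenance = prov[[as.character(g@ids[i])]])
  })
  edges <- lapply(seq_len(nrow(g@edges)), function(i) as.integer(g@edges[i, ]))
  jsonlite::write_json(list(dim = graphDim(g), nodes = nodes, edges = edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Registration error against ground truth
#'
#' Per-node Euclidean distance between each fused sensed position and its
#' true corresponding position, summarized for synthetic experiments with
#' known correspondence.
#'
#' @param fused a [FusedGraph-class].
#' @param truth data.frame mapping \code{sensedId} either to \code{refId}
#'   (true positions looked up in the reference graph) or directly to true
#'   coordinates \code{x,y(,z)}.
#' @param tol tolerance for the within-tolerance fraction; default 2\% of
#'   the largest reference extent.
#' @return list with \code{perNode} (data.frame of errors), \code{mean},
#'   \code{median}, \code{max}, \code{fracWithin}, \code{tol} and \code{n}.
#' @export
registrationError <- function(fused, truth, tol = NULL) {
  if (is.null(tol)) tol <- 0.02 * max(graphExtent(fused@reference))
  nodes <- fusedNodes(fused)
  common <- intersect(truth$sensedId, nodes$sensedId)
  if (!length(common)) stop("no overlap between truth and fused node ids")
  if (length(common) < nrow(truth))
    warning(sprintf("%d truth id(s) absent from the fused graph; scoring the intersection",
                    nrow(truth) - length(common)))
  truth <- truth[match(common, truth$sensedId), , drop = FALSE]
  dim <- graphDim(fused@reference)
  cn <- c("x", "y", "z")[seq_len(dim)]
  truePos <- if ("refId" %in% names(truth)) {
    .posOf(fused@reference, truth$refId)
  } else {
    as.matrix(truth[, cn])
  }
  fusedPos <- as.matrix(nodes[match(common, nodes$sensedId), cn])
  err <- sqrt(rowSums((fusedPos - truePos)^2))
  list(perNode = data.frame(sensedId = common, error = err),
       mean = mean(err), median = stats::median(err), max = max(err),
       fracWithin = mean(err <= tol), tol = tol, n = length(err))
}
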