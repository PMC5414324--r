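#' @include nsi.R
NULL

# lexicographically smallest integer sequence among equal-length candidates
.lexMin <- function(seqs) {
  best <- seqs[[1]]
  for (s in seqs[-1]) {
    k <- which(s != best)
    if (length(k) && s[k[1]] < best[k[1]]) best <- s
  }
  best
}

# delete the edges of a node-id path from an igraph working copy
.claimPath <- function(work, path) {
  v <- as.character(path)
  eids <- igraph::get_edge_ids(work, as.vector(rbind(v[-length(v)], v[-1])))
  igraph::delete_edges(work, eids[eids > 0])
}

#' Forward direction between two nodes
#'
#' Advancing direction from node \code{from} to node \code{to}: in 2D the
#' counterclockwise angle in degrees from the positive x axis, in [0, 360);
#' in 3D the normalized direction vector.
#'
#' @param graph a [VesselGraph-class].
#' @param from,to node ids.
#' @return a single angle (2D) or a unit vector (3D).
#' @export
forwardDirection <- function(graph, from, to) {
  v <- as.numeric(.posOf(graph, to) - .posOf(graph, from))
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero-length direction: coincident node positions")
  if (graphDim(graph) == 2L) (atan2(v[2], v[1]) * 180 / pi) %% 360
  else v / nv
}

#' Tortuosity of a polyline
#'
#' Arc-chord ratio: the distance accumulated between consecutive points
#' divided by the straight distance from the first point to the last.
#' Always >= 1, with equality exactly for collinear (monotone) samples.
#'
#' @param coords numeric matrix of ordered points (>= 2 rows).
#' @return tortuosity value >= 1.
#' @examples
#' pathTortuosity(rbind(c(0, 0), c(1, 0), c(1, 1)))  # 2 / sqrt(2)
#' @export
pathTortuosity <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("tortuosity needs at least 2 points")
  chord <- sqrt(sum((coords[nrow(coords), ] - coords[1, ])^2))
  if (chord == 0) stop("coincident endpoints: tortuosity undefined")
  gaps <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                        coords[-nrow(coords), , drop = FALSE])^2))
  sum(gaps) / chord
}

# features + Branch construction for an oriented member path
.makeBranch <- function(graph, id, anchor, members, kind) {
  r <- nodeRadii(graph)[as.character(members)]
  pts <- .posOf(graph, c(anchor, members))
  new("Branch", id = as.integer(id), nodes = as.integer(members),
      kind = kind, anchor = as.integer(anchor),
      terminal = as.integer(members[length(members)]),
      direction = forwardDirection(graph, anchor, members[1]),
      sumRadius = sum(r),
      tortuosity = if (nrow(pts) >= 2 &&
                       sum((pts[nrow(pts), ] - pts[1, ])^2) > 0)
                     pathTortuosity(pts) else NA_real_)
}

#' @rdname branch-accessors
setMethod("branchNodes", "Branch", function(x) x@nodes)
#' @rdname branch-accessors
setMethod("branchAnchor", "Branch", function(x) x@anchor)
#' @rdname branch-accessors
setMethod("branchTerminal", "Branch", function(x) x@terminal)
#' @rdname branch-accessors
setMethod("branchKind", "Branch", function(x) x@kind)

setMethod("show", "Branch", function(object) {
  cat(sprintf("Branch %d (%s): anchor %d -> %d nodes -> %d\n",
              object@id, object@kind, object@anchor, length(object@nodes),
              object@terminal))
  cat(sprintf("  sumRadius %.4g, tortuosity %.4g\n",
              object@sumRadius, object@tortuosity))
})

#' Decompose a vessel graph into salient-free branches
#'
#' Splits the graph at its matched structurally salient points into two kinds
#' of branches.  First, for every pair of salient nodes joined by a path
#' containing no other salient node, the hop-shortest such path becomes a
#' salient-to-salient branch.  Then, for every remaining degree-1 node
#' reachable from a salient node through a salient-free path on unclaimed
#' edges, the shortest path from its nearest salient node becomes a
#' salient-to-leaf branch.  Every edge belongs to at most one branch (claimed
#' edges are masked before later searches); edges that cannot be reached
#' without crossing an unmatched salient node remain in the residual set.
#'
#' The anchoring end of a salient-to-salient branch is the endpoint with the
#' higher \code{anchorRank} (ties to the smaller id); path ties are broken by
#' the smallest lexicographic node-id sequence, so the decomposition is
#' deterministic and independent of input ordering.
#'
#' @param graph a [VesselGraph-class].
#' @param salientIds nonempty vector of matched salient node ids.
#' @param anchorRank optional named numeric over \code{salientIds}; higher
#'   rank anchors a two-salient branch.  In the registration pipeline this is
#'   the reference-side NSI of each salient pair, so both graphs orient
#'   corresponding branches consistently.  Defaults to all-equal ranks.
#' @return list with \code{branches} (list of [Branch-class], ids 1..n in
#'   extraction order) and \code{residual} (two-column matrix of unclaimed
#'   edges).
#' @export
decomposeGraph <- function(graph, salientIds, anchorRank = NULL) {
  salientIds <- sort(unique(as.integer(salientIds)))
  if (!length(salientIds)) stop("salientIds must be nonempty")
  if (!all(salientIds %in% graph@ids)) stop("unknown salient id(s)")
  if (is.null(anchorRank))
    anchorRank <- stats::setNames(rep(0, length(salientIds)),
                                  as.character(salientIds))
  work <- .asIgraph(graph)
  branches <- list()
  nextId <- 1L

  pickPath <- function(sub, from, to) {
    # all hop-shortest paths from 'from' to 'to', as id sequences
    ap <- suppressWarnings(
      igraph::all_shortest_paths(sub, from = as.character(from),
                                 to = as.character(to)))
    paths <- lapply(ap$vpaths %||% ap$res,
                    function(p) as.integer(names(p)))
    paths <- Filter(function(p) length(p) >= 2, paths)
    if (!length(paths)) return(NULL)
    .lexMin(paths)
  }

  # kind 1: salient-to-salient
  if (length(salientIds) >= 2) {
    prs <- utils::combn(salientIds, 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      others <- setdiff(salientIds, c(a, b))
      sub <- igraph::delete_vertices(work, as.character(others))
      ra <- anchorRank[as.character(a)]; rb <- anchorRank[as.character(b)]
      anchor <- if (rb > ra) b else a
      far <- if (anchor == a) b else a
      path <- pickPath(sub, anchor, far)
      if (is.null(path)) next
      branches[[nextId]] <- .makeBranch(graph, nextId, anchor, path[-1],
                                        "salient-salient")
      work <- .claimPath(work, path)
      nextId <- nextId + 1L
    }
  }

  # kind 2: salient-to-leaf, on unclaimed edges
  leaves <- sort(setdiff(graph@ids[nodeDegree(graph) == 1L], salientIds))
  for (leaf in leaves) {
    best <- NULL
    for (s in salientIds) {
      sub <- igraph::delete_vertices(work,
                                     as.character(setdiff(salientIds, s)))
      path <- pickPath(sub, s, leaf)
      if (is.null(path)) next
      if (is.null(best) || length(path) < length(best) ||
          (length(path) == length(best) &&
           !identical(.lexMin(list(path, best)), best)))
        best <- path
    }
    if (is.null(best)) next
    branches[[nextId]] <- .makeBranch(graph, nextId, best[1], best[-1],
                                      "salient-leaf")
    work <- .claimPath(work, best)
    nextId <- nextId + 1L
  }

  res <- igraph::as_edgelist(work)
  residual <- matrix(as.integer(res), ncol = 2)
  colnames(residual) <- c("from", "to")
  list(branches = branches, residual = residual)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Branch feature table
#'
#' One row per branch with the three matching features, mirroring the
#' branch-property tables of the method (tortuosity, sum radius, forward
#' direction of the starting point).
#'
#' @param branches list of [Branch-class].
#' @return data.frame with columns \code{branchId}, \code{kind},
#'   \code{anchor}, \code{terminal}, \code{nNodes}, \code{tortuosity},
#'   \code{sumRadius}, and the forward direction (one angle column in 2D,
#'   three vector columns in 3D).
#' @export
branchTable <- function(branches) {
  if (!length(branches)) {
    return(data.frame(branchId = integer(0), kind = character(0),
                      anchor = integer(0), terminal = integer(0),
                      nNodes = integer(0), tortuosity = numeric(0),
                      sumRadius = numeric(0), forwardDirection = numeric(0)))
  }
  base <- data.frame(
    branchId = vapply(branches, function(b) b@id, integer(1)),
    kind = vapply(branches, branchKind, character(1)),
    anchor = vapply(branches, branchAnchor, integer(1)),
    terminal = vapply(branches, branchTerminal, integer(1)),
    nNodes = vapply(branches, function(b) length(b@nodes), integer(1)),
    tortuosity = vapply(branches, function(b) b@tortuosity, numeric(1)),
    sumRadius = vapply(branches, function(b) b@sumRadius, numeric(1)))
  if (length(branches[[1]]@direction) == 1) {
    base$forwardDirection <- vapply(branches, function(b) b@direction,
                                    numeric(1))
  } else {
    d <- t(vapply(branches, function(b) b@direction, numeric(3)))
    base$dirX <- d[, 1]; base$dirY <- d[, 2]; base$dirZ <- d[, 3]
  }
  base
}

#' @rdname branchTable
#' @param path output TSV path.
#' @export
exportBranchTable <- function(branches, path) {
  utils::write.table(branchTable(branches), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
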