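#' @include AllGenerics.R
NULL

#' Construct a vessel centerline graph
#'
#' @param ids integer node identifiers (unique).
#' @param coords numeric matrix of node positions, one row per node, with 2
#'   or 3 columns.  Coordinates are continuous image/physical units.
#' @param radius positive numeric node radii.
#' @param edges two-column matrix (or empty) of undirected id pairs.
#' @param dim 2 or 3; defaults to \code{ncol(coords)}.
#' @return a [VesselGraph-class] object.
#' @examples
#' g <- VesselGraph(1:3, cbind(0:2, 0), radius = c(1, 1, 1),
#'                  edges = rbind(c(1, 2), c(2, 3)))
#' nNodes(g); nodeDegree(g)
#' @export
VesselGraph <- function(ids, coords, radius, edges = NULL, dim = ncol(coords)) {
  ids <- as.integer(ids)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")[seq_len(ncol(coords))]
  if (is.null(edges) || length(edges) == 0)
    edges <- matrix(integer(0), ncol = 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  colnames(edges) <- c("from", "to")
  new("VesselGraph", ids = ids, coords = coords, radius = as.numeric(radius),
      edges = edges, dim = as.integer(dim))
}

#' @rdname vesselgraph-accessors
setMethod("nNodes", "VesselGraph", function(x) length(x@ids))
#' @rdname vesselgraph-accessors
setMethod("nEdges", "VesselGraph", function(x) nrow(x@edges))
#' @rdname vesselgraph-accessors
setMethod("nodeIds", "VesselGraph", function(x) x@ids)
#' @rdname vesselgraph-accessors
setMethod("nodeCoords", "VesselGraph", function(x) {
  m <- x@coords
  rownames(m) <- as.character(x@ids)
  m
})
#' @rdname vesselgraph-accessors
setMethod("nodeRadii", "VesselGraph", function(x) {
  stats::setNames(x@radius, as.character(x@ids))
})
#' @rdname vesselgraph-accessors
setMethod("graphEdges", "VesselGraph", function(x) x@edges)
#' @rdname vesselgraph-accessors
setMethod("graphDim", "VesselGraph", function(x) x@dim)
#' @rdname vesselgraph-accessors
setMethod("graphExtent", "VesselGraph", function(x) {
  if (nNodes(x) == 0) return(rep(0, x@dim))
  apply(x@coords, 2, function(v) diff(range(v)))
})

setMethod("show", "VesselGraph", function(object) {
  cat(sprintf("VesselGraph: %d nodes, %d edges, dim %d\n",
              nNodes(object), nEdges(object), graphDim(object)))
  if (nNodes(object)) {
    cat(sprintf("  extent: %s\n",
                paste(signif(graphExtent(object), 4), collapse = " x ")))
    cat(sprintf("  radius: [%.3g, %.3g]\n",
                min(object@radius), max(object@radius)))
  }
})

#' Node degree
#'
#' Number of edges incident to each requested node.
#'
#' @param graph a [VesselGraph-class].
#' @param ids node ids; default all nodes.
#' @return named integer vector of degrees.
#' @export
nodeDegree <- function(graph, ids = nodeIds(graph)) {
  if (!all(ids %in% graph@ids)) {
    stop("unknown node id(s): ",
         paste(setdiff(ids, graph@ids), collapse = ", "))
  }
  tab <- table(factor(c(graph@edges[, 1], graph@edges[, 2]),
                      levels = graph@ids))
  d <- as.integer(tab)[match(ids, graph@ids)]
  stats::setNames(d, as.character(ids))
}

# internal: row index of each id
.rowOf <- function(graph, ids) match(ids, graph@ids)

# internal: positions of the given ids, rows in request order
.posOf <- function(graph, ids) graph@coords[.rowOf(graph, ids), , drop = FALSE]

# internal: igraph view with vertex names = node ids
.asIgraph <- function(graph) {
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(graph@edges[, 1]),
                   to = as.character(graph@edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(graph@ids)))
}

#' Drop small isolated components
#'
#' Isolated connected components of fewer than \code{minNodes} nodes are
#' removed with a warning: stray fragments this small are usually tracing
#' noise or trivial vessels and are not registered.
#'
#' @param graph a [VesselGraph-class].
#' @param minNodes minimum component size kept (default 3).
#' @return the pruned graph.
#' @export
pruneSmallComponents <- function(graph, minNodes = 3L) {
  if (nNodes(graph) == 0) return(graph)
  comp <- igraph::components(.asIgraph(graph))
  keepComp <- which(comp$csize >= minNodes)
  keep <- graph@ids[comp$membership %in% keepComp]
  nDrop <- nNodes(graph) - length(keep)
  if (nDrop > 0) {
    warning(sprintf("dropped %d node(s) in isolated components of < %d nodes",
                    nDrop, minNodes))
    rows <- .rowOf(graph, keep)
    e <- graph@edges
    e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
    graph <- VesselGraph(keep, graph@coords[rows, , drop = FALSE],
                         graph@radius[rows], e, dim = graph@dim)
  }
  graph
}

#' Extract a subgraph by node ids
#'
#' @param graph a [VesselGraph-class].
#' @param ids nodes to keep.
#' @return the induced subgraph.
#' @export
subsetGraph <- function(graph, ids) {
  rows <- .rowOf(graph, ids)
  if (anyNA(rows)) stop("unknown node id(s)")
  e <- graph@edges
  e <- e[e[, 1] %in% ids & e[, 2] %in% ids, , drop = FALSE]
  VesselGraph(ids, graph@coords[rows, , drop = FALSE], graph@radius[rows],
              e, dim = graph@dim)
}
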