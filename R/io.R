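#' @include vessel-graph.R
NULL

#' Read a vessel tree from an SWC file
#'
#' SWC is the standard plain-text interchange for traced tubular structures:
#' one record per line, \code{id type x y z radius parent}, with
#' \code{parent = -1} for roots and \code{#} comments.  Each record becomes a
#' node, each (id, parent) pointer an undirected edge.  Planar tracings are
#' stored with a constant z and detected as 2D on read.
#'
#' @param path file path.
#' @param dropIsolated drop isolated components of fewer than 3 nodes (with
#'   a warning), which are not registered; default TRUE.
#' @return a [VesselGraph-class].
#' @seealso [writeSWC()], [readGraphJSON()]
#' @export
readSWC <- function(path, dropIsolated = TRUE) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  recs <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 7)
      stop(sprintf("line %d: expected 7 fields, got %d", i, length(f)))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric field", i))
    c(line = i, v)
  })
  if (!length(recs)) {
    return(VesselGraph(integer(0), matrix(numeric(0), ncol = 3),
                       numeric(0), NULL, dim = 3L))
  }
  m <- do.call(rbind, recs)
  colnames(m) <- c("line", "id", "type", "x", "y", "z", "radius", "parent")
  dup <- which(duplicated(m[, "id"]))
  if (length(dup))
    stop(sprintf("line %d: duplicate node id %d", m[dup[1], "line"],
                 as.integer(m[dup[1], "id"])))
  bad <- which(m[, "radius"] <= 0)
  if (length(bad))
    stop(sprintf("line %d: non-positive radius %g", m[bad[1], "line"],
                 m[bad[1], "radius"]))
  hasParent <- m[, "parent"] != -1
  orphan <- which(hasParent & !(m[, "parent"] %in% m[, "id"]))
  if (length(orphan))
    stop(sprintf("line %d: parent %d references unknown id",
                 m[orphan[1], "line"], as.integer(m[orphan[1], "parent"])))
  dim <- if (length(unique(m[, "z"])) == 1) 2L else 3L
  coords <- m[, c("x", "y", "z")[seq_len(dim)], drop = FALSE]
  edges <- cbind(m[hasParent, "id"], m[hasParent, "parent"])
  g <- VesselGraph(as.integer(m[, "id"]), coords, m[, "radius"], edges,
                   dim = dim)
  if (dropIsolated) g <- pruneSmallComponents(g) else g
}

#' Write a vessel tree to an SWC file
#'
#' The graph must be acyclic (SWC encodes trees through parent pointers);
#' cyclic graphs must use [writeGraphJSON()].  2D graphs are written with
#' z = 0.  Records are emitted in ascending id order for diffability.
#'
#' @param graph a [VesselGraph-class] without cycles.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeSWC <- function(graph, path) {
  nComp <- igraph::components(.asIgraph(graph))$no
  if (nEdges(graph) > nNodes(graph) - nComp)
    stop("graph contains a cycle; SWC cannot encode cycles (use writeGraphJSON)")
  parent <- stats::setNames(rep(-1L, nNodes(graph)), as.character(graph@ids))
  ig <- .asIgraph(graph)
  comp <- igraph::components(ig)
  named <- names(igraph::V(ig))
  for (ci in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == ci]
    root <- members[which.min(as.integer(members))]
    bfs <- igraph::bfs(ig, root = root, unreachable = FALSE, father = TRUE)
    fa <- as.integer(bfs$father)          # parent vertex index or NA
    for (v in members) {
      fi <- fa[match(v, named)]
      if (!is.na(fi)) parent[v] <- as.integer(named[fi])
    }
  }
  ord <- order(graph@ids)
  z <- if (graphDim(graph) == 2L) rep(0, nNodes(graph)) else graph@coords[, 3]
  lines <- sprintf("%d %d %.10g %.10g %.10g %.10g %d",
                   graph@ids[ord], 2L,
                   graph@coords[ord, 1], graph@coords[ord, 2], z[ord],
                   graph@radius[ord],
                   parent[as.character(graph@ids[ord])])
  writeLines(c("# id type x y z radius parent", lines), path)
  invisible(path)
}

#' Read/write a vessel graph in the JSON graph dialect
#'
#' SWC cannot encode cycles, which cerebral vasculature can contain; general
#' graphs travel in a small JSON schema instead:
#' \preformatted{{"dim": 2, "nodes": [{"id": 1, "pos": [x, y], "radius": r}, ...],
#'  "edges": [[a, b], ...]}}
#' Writing then reading reproduces the graph node-for-node and
#' edge-for-edge; writers emit deterministic key and record order.
#'
#' @param path file path.
#' @param dropIsolated as in [readSWC()]; default FALSE for round-trip
#'   fidelity.
#' @return \code{readGraphJSON}: a [VesselGraph-class];
#'   \code{writeGraphJSON}: invisibly, \code{path}.
#' @export
readGraphJSON <- function(path, dropIsolated = FALSE) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fail <- function(where, what) stop(sprintf("%s: %s", where, what))
  if (!is.list(x)) fail("$", "top level must be an object")
  for (k in c("dim", "nodes", "edges"))
    if (is.null(x[[k]])) fail(paste0("$.", k), "missing required key")
  dim <- as.integer(x$dim)
  if (!(dim %in% c(2L, 3L))) fail("$.dim", "must be 2 or 3")
  n <- length(x$nodes)
  ids <- integer(n); radius <- numeric(n)
  coords <- matrix(NA_real_, n, dim)
  for (i in seq_len(n)) {
    nd <- x$nodes[[i]]
    here <- sprintf("$.nodes[%d]", i)
    for (k in c("id", "pos", "radius"))
      if (is.null(nd[[k]])) fail(here, paste0("missing key '", k, "'"))
    if (length(nd$pos) != dim)
      fail(paste0(here, ".pos"), sprintf("expected %d coordinates", dim))
    if (!is.numeric(nd$radius) || nd$radius <= 0)
      fail(paste0(here, ".radius"), "must be a positive number")
    ids[i] <- as.integer(nd$id)
    coords[i, ] <- as.numeric(unlist(nd$pos))
    radius[i] <- as.numeric(nd$radius)
  }
  if (anyDuplicated(ids)) fail("$.nodes", "duplicate node id")
  m <- length(x$edges)
  edges <- matrix(integer(0), ncol = 2)
  if (m) {
    for (i in seq_len(m)) {
      e <- unlist(x$edges[[i]])
      here <- sprintf("$.edges[%d]", i)
      if (length(e) != 2) fail(here, "must be a pair [a, b]")
      if (e[1] == e[2]) fail(here, "self loop")
      if (!all(e %in% ids)) fail(here, "endpoint references unknown node id")
    }
    edges <- t(vapply(x$edges, function(e) as.integer(unlist(e)), integer(2)))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    d <- which(duplicated(key))
    if (length(d)) fail(sprintf("$.edges[%d]", d[1]), "duplicate edge")
  }
  g <- VesselGraph(ids, coords, radius, edges, dim = dim)
  if (dropIsolated) pruneSmallComponents(g) else g
}

#' @rdname readGraphJSON
#' @param graph a [VesselGraph-class].
#' @export
writeGraphJSON <- function(graph, path) {
  ord <- order(graph@ids)
  nodes <- lapply(ord, function(i) {
    list(id = graph@ids[i], pos = as.numeric(graph@coords[i, ]),
         radius = graph@radius[i])
  })
  e <- graph@edges
  edges <- lapply(seq_len(nrow(e)), function(i) as.integer(e[i, ]))
  jsonlite::write_json(list(dim = graphDim(graph), nodes = nodes,
                            edges = edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
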