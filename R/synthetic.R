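#' @include fusion.R
NULL

#' Configuration of the synthetic vascular tree generator
#'
#' Describes a bifurcating tree of the scale used throughout the method's
#' experiments: a root segment splitting 2-way at every level, with radii
#' decaying from root to leaf, smooth in-segment curvature, and around
#' 100-150 centerline nodes under the defaults (depth 4, 7 nodes per
#' segment: 15 segments, 106 nodes).
#'
#' @param dim 2 or 3.
#' @param depth number of bifurcation levels (depth d gives 2^d - 1
#'   segments... counting: 1 + 2 + ... + 2^(depth-1)).
#' @param segmentLength mean segment length, image units.
#' @param segmentLengthSd standard deviation of segment length.
#' @param rootRadius vessel radius at the root, image units.
#' @param radiusDecay per-level multiplicative radius decay in (0, 1].
#' @param curvature in-segment bow amplitude as a fraction of segment
#'   length.
#' @param nodesPerSegment centerline samples per segment (the distal sample
#'   is the junction or leaf node).
#' @param branchAngle half-opening angle of a bifurcation, degrees.
#' @param seed integer seed; all generator randomness flows from it.
#' @return validated config list of class \code{treeConfig}.
#' @export
treeConfig <- function(dim = 2L, depth = 4L, segmentLength = 8,
                       segmentLengthSd = 1.2, rootRadius = 2.5,
                       radiusDecay = 0.8, curvature = 0.15,
                       nodesPerSegment = 7L, branchAngle = 35, seed = 1L) {
  stopifnot(dim %in% c(2L, 3L), depth >= 1, segmentLength > 0,
            segmentLengthSd >= 0, rootRadius > 0,
            radiusDecay > 0, radiusDecay <= 1, curvature >= 0,
            nodesPerSegment >= 2, branchAngle > 0, branchAngle < 90)
  structure(list(dim = as.integer(dim), depth = as.integer(depth),
                 segmentLength = segmentLength,
                 segmentLengthSd = segmentLengthSd,
                 rootRadius = rootRadius, radiusDecay = radiusDecay,
                 curvature = curvature,
                 nodesPerSegment = as.integer(nodesPerSegment),
                 branchAngle = branchAngle, seed = as.integer(seed)),
            class = "treeConfig")
}

#' Configuration of the synthetic deformation / corruption model
#'
#' Emulates the differences between a reference and a sensed acquisition:
#' a smooth non-linear warp (sum of Gaussian radial bumps, normalized so the
#' maximum node displacement equals \code{warpAmplitude} times the extent),
#' multiplicative per-node radius noise, short low-radius interference spurs
#' attached next to bifurcations, and deletion of terminal leaf branches.
#'
#' @param warpAmplitude maximum displacement as a fraction of the graph
#'   extent (default 0.05).
#' @param warpScale bump width as a fraction of the extent (default 0.5).
#' @param nBumps number of radial displacement bumps (default 3).
#' @param radiusNoiseSd fractional radius noise standard deviation
#'   (default 0.10).
#' @param spurCount number of interference spurs to attach near
#'   bifurcations (default 2).
#' @param deletionProb probability that each terminal leaf branch is
#'   deleted (default 0).
#' @param deleteCount optional exact number of leaf branches to delete
#'   (overrides \code{deletionProb}).
#' @param seed integer seed.
#' @return validated config list of class \code{deformConfig}.
#' @export
deformConfig <- function(warpAmplitude = 0.05, warpScale = 0.5, nBumps = 3L,
                         radiusNoiseSd = 0.10, spurCount = 2L,
                         deletionProb = 0, deleteCount = NULL, seed = 1L) {
  stopifnot(warpAmplitude >= 0, warpScale > 0, nBumps >= 1,
            radiusNoiseSd >= 0, spurCount >= 0,
            deletionProb >= 0, deletionProb <= 1)
  structure(list(warpAmplitude = warpAmplitude, warpScale = warpScale,
                 nBumps = as.integer(nBumps), radiusNoiseSd = radiusNoiseSd,
                 spurCount = as.integer(spurCount),
                 deletionProb = deletionProb,
                 deleteCount = if (is.null(deleteCount)) NULL
                               else as.integer(deleteCount),
                 seed = as.integer(seed)),
            class = "deformConfig")
}

# size-safe sample (never the 1:n expansion of a length-1 x)
.sample <- function(x, size) x[sample.int(length(x), size)]

# unit vector rotated from 'dir' by angle (2D) or by angle around a random
# axis component (3D)
.rotate <- function(dir, angleDeg, dim) {
  a <- angleDeg * pi / 180
  if (dim == 2L) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    as.numeric(R %*% dir)
  } else {
    # rotate within the plane spanned by dir and a random perpendicular
    p <- stats::rnorm(3)
    p <- p - sum(p * dir) * dir
    np <- sqrt(sum(p^2))
    if (np < 1e-12) p <- c(dir[2], -dir[1], 0) else p <- p / np
    cos(a) * dir + sin(a) * p
  }
}

#' Generate a ground-truthed synthetic vascular tree
#'
#' Deterministic for a fixed seed.  Radii decay from root to leaf by the
#' configured factor with mild lognormal jitter, segments bow smoothly
#' sideways (curvature), and every level splits 2-way at the configured
#' branch angle with jitter.
#'
#' @param config a [treeConfig()].
#' @return list with \code{graph} (a [VesselGraph-class]) and \code{labels}
#'   (data.frame: \code{id}, \code{segment}, \code{level},
#'   \code{isJunction}).
#' @export
generateTree <- function(config) {
  stopifnot(inherits(config, "treeConfig"))
  set.seed(config$seed)
  dim <- config$dim
  nps <- config$nodesPerSegment
  ids <- integer(0); coords <- NULL; radius <- numeric(0)
  edges <- NULL; segLab <- integer(0); levLab <- integer(0)
  nextId <- 1L; segId <- 0L

  addNode <- function(pos, r, seg, lev) {
    id <- nextId
    nextId <<- nextId + 1L
    ids <<- c(ids, id)
    coords <<- rbind(coords, pos)
    radius <<- c(radius, max(r, 0.05))
    segLab <<- c(segLab, seg)
    levLab <<- c(levLab, lev)
    id
  }

  grow <- function(fromId, fromPos, dir, level, rStart) {
    segId <<- segId + 1L
    seg <- segId
    len <- max(0.3 * config$segmentLength,
               stats::rnorm(1, config$segmentLength, config$segmentLengthSd))
    rEnd <- rStart * config$radiusDecay *
      exp(stats::rnorm(1, 0, 0.05))
    # perpendicular bow direction
    perp <- .rotate(dir, 90, dim)
    bow <- config$curvature * len * stats::runif(1, -1, 1)
    prev <- fromId
    endId <- NA_integer_
    for (k in seq_len(nps)) {
      t <- k / nps
      pos <- fromPos + t * len * dir + bow * sin(pi * t) * perp
      r <- rStart + t * (rEnd - rStart)
      id <- addNode(pos, r, seg, level)
      edges <<- rbind(edges, c(prev, id))
      prev <- id
      endId <- id
    }
    if (level < config$depth) {
      for (s in c(-1, 1)) {
        ang <- s * config$branchAngle * stats::runif(1, 0.7, 1.3)
        grow(endId, coords[match(endId, ids), ], .rotate(dir, ang, dim),
             level + 1L, rEnd)
      }
    }
    endId
  }

  rootDir <- if (dim == 2L) c(0, 1) else c(0, 0, 1)
  rootId <- addNode(rep(0, dim), config$rootRadius, 0L, 0L)
  grow(rootId, rep(0, dim), rootDir, 1L, config$rootRadius)

  g <- VesselGraph(ids, coords, radius, edges, dim = dim)
  if (nNodes(g) < 3) stop("config produced fewer than 3 nodes")
  deg <- nodeDegree(g)
  labels <- data.frame(id = ids, segment = segLab, level = levLab,
                       isJunction = as.integer(deg[as.character(ids)]) >= 3L)
  list(graph = g, labels = labels)
}

# terminal leaf branches: list of id vectors from (exclusive) nearest
# junction to leaf
.leafBranches <- function(graph) {
  deg <- nodeDegree(graph)
  adj <- .adjacency(graph)
  leaves <- graph@ids[as.integer(deg) == 1L]
  lapply(leaves, function(leaf) {
    path <- leaf
    cur <- as.character(leaf); prev <- NA_character_
    repeat {
      nb <- setdiff(adj[[cur]], prev)
      if (length(nb) != 1) break
      nxt <- nb[1]
      if (as.integer(deg[nxt]) >= 3L) break
      path <- c(path, as.integer(nxt))
      prev <- cur; cur <- nxt
    }
    path
  })
}

#' Deform and corrupt a graph into a synthetic sensed copy
#'
#' Applies, in order: deletion of terminal leaf branches, the smooth
#' low-frequency warp, radius noise, and interference spurs near surviving
#' bifurcations; surviving original nodes are renumbered consecutively and
#' the true correspondence is returned.
#'
#' @param graph a [VesselGraph-class] (the reference).
#' @param config a [deformConfig()].
#' @return list with \code{graph} (the sensed copy) and \code{map}
#'   (data.frame \code{sensedId}, \code{refId}; spur nodes have no entry).
#' @export
deformGraph <- function(graph, config) {
  stopifnot(inherits(config, "deformConfig"))
  set.seed(config$seed)
  ext <- max(graphExtent(graph))
  dim <- graphDim(graph)
  keep <- graph@ids

  # leaf-branch deletion
  lb <- .leafBranches(graph)
  if (length(lb)) {
    del <- if (!is.null(config$deleteCount)) {
      if (config$deleteCount > 0)
        .sample(seq_along(lb), min(config$deleteCount, length(lb)))
      else integer(0)
    } else {
      which(stats::runif(length(lb)) < config$deletionProb)
    }
    if (length(del)) keep <- setdiff(keep, unlist(lb[del]))
  }
  rows <- .rowOf(graph, keep)
  coords <- graph@coords[rows, , drop = FALSE]
  radius <- graph@radius[rows]
  e <- graph@edges
  e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]

  # smooth warp: sum of Gaussian radial bumps, normalized to the amplitude
  if (config$warpAmplitude > 0) {
    lo <- apply(graph@coords, 2, min); hi <- apply(graph@coords, 2, max)
    disp <- matrix(0, nrow(coords), dim)
    for (b in seq_len(config$nBumps)) {
      center <- lo + stats::runif(dim) * (hi - lo)
      u <- stats::rnorm(dim); u <- u / sqrt(sum(u^2))
      sig <- config$warpScale * ext
      w <- exp(-rowSums((coords - rep(center, each = nrow(coords)))^2) /
               (2 * sig^2))
      disp <- disp + outer(w, u)
    }
    mx <- max(sqrt(rowSums(disp^2)))
    if (mx > 0)
      coords <- coords + disp * (config$warpAmplitude * ext / mx)
  }

  # multiplicative radius noise, floored
  if (config$radiusNoiseSd > 0)
    radius <- pmax(0.05,
                   radius * (1 + stats::rnorm(length(radius),
                                              0, config$radiusNoiseSd)))

  # renumber surviving originals consecutively
  ord <- order(keep)
  newId <- stats::setNames(seq_along(keep), as.character(keep[ord]))
  ids2 <- as.integer(newId[as.character(keep)])
  e2 <- cbind(as.integer(newId[as.character(e[, 1])]),
              as.integer(newId[as.character(e[, 2])]))
  map <- data.frame(sensedId = ids2, refId = keep)
  map <- map[order(map$sensedId), ]
  rownames(map) <- NULL

  # interference spurs near surviving bifurcations
  tmp <- VesselGraph(ids2, coords, radius, e2, dim = dim)
  if (config$spurCount > 0) {
    deg <- nodeDegree(tmp)
    junctions <- ids2[as.integer(deg) >= 3L]
    adj <- .adjacency(tmp)
    nId <- max(ids2)
    if (length(junctions)) {
      at <- .sample(rep(junctions, length.out = max(config$spurCount,
                                                    length(junctions))),
                    config$spurCount)
      for (j in at) {
        # attach at a neighbor of the bifurcation (near, not at, the fork)
        base <- as.integer(.sample(adj[[as.character(j)]], 1))
        bRow <- match(base, nodeIds(tmp))
        u <- stats::rnorm(dim); u <- u / sqrt(sum(u^2))
        len <- 0.08 * ext
        rSpur <- 0.3 * tmp@radius[bRow]
        nSpur <- 2L
        prev <- base
        cs <- nodeCoords(tmp); rr <- nodeRadii(tmp)
        newIds <- nodeIds(tmp); newE <- tmp@edges
        for (k in seq_len(nSpur)) {
          nId <- nId + 1L
          pos <- cs[bRow, ] + (k / nSpur) * len * u
          newIds <- c(newIds, nId)
          cs <- rbind(cs, pos)
          rr <- c(rr, max(0.05, rSpur))
          newE <- rbind(newE, c(prev, nId))
          prev <- nId
        }
        tmp <- VesselGraph(newIds, cs, as.numeric(rr), newE, dim = dim)
      }
    }
  }
  list(graph = tmp, map = map)
}

#' Generate a full synthetic registration pair
#'
#' Convenience wrapper: generates the reference tree, deforms it into the
#' sensed copy, and optionally writes the triplet (reference SWC, sensed
#' SWC, ground-truth TSV) to a directory.
#'
#' @param tree a [treeConfig()].
#' @param deform a [deformConfig()].
#' @param dir optional output directory; created if needed.
#' @return list with \code{reference}, \code{sensed} ([VesselGraph-class])
#'   and \code{map} (ground-truth correspondence), plus \code{files} when
#'   written.
#' @export
simulatePair <- function(tree = treeConfig(), deform = deformConfig(),
                         dir = NULL) {
  refOut <- generateTree(tree)
  senOut <- deformGraph(refOut$graph, deform)
  out <- list(reference = refOut$graph, sensed = senOut$graph,
              map = senOut$map, labels = refOut$labels)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(reference = file.path(dir, "reference.swc"),
               sensed = file.path(dir, "sensed.swc"),
               truth = file.path(dir, "truth.tsv"))
    writeSWC(out$reference, files[["reference"]])
    writeSWC(out$sensed, files[["sensed"]])
    utils::write.table(out$map, files[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$files <- files
  }
  out
}
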