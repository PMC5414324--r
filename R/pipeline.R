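#' @include synthetic.R
NULL

#' Effective parameters of a registration run
#'
#' Collects the adjustable parameters of the pipeline with the method's
#' defaults: the salient-matching neighborhood (5\% of the reference
#' extent), the maximum allowable angular difference between branch forward
#' directions (60 degrees), the allowable fractional summed-radius
#' difference (30\%), the node-matching search window (20\% of branch node
#' count), and the NSI hop horizon and decay.
#'
#' @param rhoFrac salient neighborhood fraction of the reference extent.
#' @param maxAngle maximum branch direction difference, degrees, in
#'   (0, 180].
#' @param radiusTol fractional summed-radius tolerance, in (0, 1].
#' @param wFrac node-matching window fraction, in (0, 1].
#' @param nsiH NSI hop horizon.
#' @param nsiLambda NSI decay in (0, 1].
#' @param minComponent smallest isolated component registered.
#' @param seed integer seed recorded with the run.
#' @return validated parameter list of class \code{runConfig}.
#' @export
runConfig <- function(rhoFrac = 0.05, maxAngle = 60, radiusTol = 0.30,
                      wFrac = 0.20, nsiH = 2L, nsiLambda = 0.5,
                      minComponent = 3L, seed = 1L) {
  stopifnot(rhoFrac > 0, rhoFrac <= 1, maxAngle > 0, maxAngle <= 180,
            radiusTol > 0, radiusTol <= 1, wFrac > 0, wFrac <= 1,
            nsiH >= 0, nsiLambda > 0, nsiLambda <= 1)
  structure(list(rhoFrac = rhoFrac, maxAngle = maxAngle,
                 radiusTol = radiusTol, wFrac = wFrac,
                 nsiH = as.integer(nsiH), nsiLambda = nsiLambda,
                 minComponent = as.integer(minComponent),
                 seed = as.integer(seed)),
            class = "runConfig")
}

#' Register a sensed vessel graph onto a reference
#'
#' Runs the full pipeline: small-component pruning, NSI computation,
#' salient-point matching, branch decomposition anchored at the matched
#' salient points (both sides oriented by the reference-side NSI), branch
#' matching by the sequential criteria, circuit conversion and integrated
#' voltage sequences, windowed node matching on the scaled magnitudes, and
#' fusion.
#'
#' Branch pairs whose sensed voltage-magnitude sequence is degenerate
#' (a single node, or zero range so the linear scaling is undefined) fall
#' back to proportional index mapping with zero voltage difference and the
#' clamp flag set.
#'
#' @param ref,sensed [VesselGraph-class] objects of equal dimensionality.
#' @param config a [runConfig()].
#' @return a [VesselRegistration-class]; fails with an error when no
#'   salient pair can be established (e.g. under a large initial rotation
#'   the corresponding salient points fall beyond the allowed neighborhood,
#'   a stated limitation of the method).
#' @export
registerVessels <- function(ref, sensed, config = runConfig()) {
  stopifnot(is(ref, "VesselGraph"), is(sensed, "VesselGraph"),
            graphDim(ref) == graphDim(sensed))
  ref <- pruneSmallComponents(ref, config$minComponent)
  sensed <- pruneSmallComponents(sensed, config$minComponent)
  nsiRef <- computeNSI(ref, h = config$nsiH, lambda = config$nsiLambda)
  nsiSen <- computeNSI(sensed, h = config$nsiH, lambda = config$nsiLambda)
  pairs <- suppressWarnings(
    matchSalientPoints(ref, sensed, nsiRef, nsiSen, config$rhoFrac))
  if (nrow(pairs) == 0)
    stop("no salient pairs found; registration cannot proceed")

  rankRef <- stats::setNames(pairs$refNsi, as.character(pairs$refId))
  rankSen <- stats::setNames(pairs$refNsi, as.character(pairs$sensedId))
  decRef <- decomposeGraph(ref, pairs$refId, rankRef)
  decSen <- decomposeGraph(sensed, pairs$sensedId, rankSen)

  bm <- matchBranches(decRef$branches, decSen$branches, pairs,
                      maxAngle = config$maxAngle,
                      radiusTol = config$radiusTol)

  refById <- stats::setNames(decRef$branches,
    vapply(decRef$branches, function(b) as.character(b@id), character(1)))
  senById <- stats::setNames(decSen$branches,
    vapply(decSen$branches, function(b) as.character(b@id), character(1)))
  nodeMatches <- list()
  for (k in seq_len(nrow(bm$pairs))) {
    rb <- refById[[as.character(bm$pairs$refBranch[k])]]
    sb <- senById[[as.character(bm$pairs$sensedBranch[k])]]
    Va <- voltageMagnitude(
      integratedVoltageSequence(branchToCircuit(rb, ref, nsiRef)))
    Vb <- voltageMagnitude(
      integratedVoltageSequence(branchToCircuit(sb, sensed, nsiSen)))
    m <- if (length(Vb) == 1 || diff(range(Vb)) == 0 ||
             diff(range(Va)) == 0) {
      .proportionalMatch(length(Va), length(Vb))
    } else {
      matchNodes(Va, scaleSequence(Vb, Va)$scaled, config$wFrac)
    }
    nodeMatches[[as.character(rb@id)]] <- m
  }

  fused <- fuseGraphs(ref, sensed, pairs, decRef$branches, decSen$branches,
                      bm$pairs, nodeMatches)
  new("VesselRegistration", reference = ref, sensed = sensed,
      nsiRef = nsiRef, nsiSensed = nsiSen, salientPairs = pairs,
      refBranches = decRef$branches, sensedBranches = decSen$branches,
      refResidual = decRef$residual, sensedResidual = decSen$residual,
      branchPairs = bm$pairs, nodeMatches = nodeMatches, fused = fused,
      parameters = unclass(config))
}

# degenerate-sequence fallback: proportional index mapping, flagged
.proportionalMatch <- function(nA, nB) {
  i <- seq_len(nB)
  j <- if (nB == 1) rep(1L, nB)
       else 1L + as.integer(round((i - 1) * (nA - 1) / (nB - 1)))
  data.frame(i = i, leadingNode = j, deltaV = 0, baseNode = j,
             clamped = TRUE)
}

setMethod("show", "VesselRegistration", function(object) {
  cat("VesselRegistration\n")
  cat(sprintf("  reference: %d nodes / sensed: %d nodes (dim %d)\n",
              nNodes(object@reference), nNodes(object@sensed),
              graphDim(object@reference)))
  cat(sprintf("  salient pairs: %d\n", nrow(object@salientPairs)))
  cat(sprintf("  branches: %d ref, %d sensed, %d paired\n",
              length(object@refBranches), length(object@sensedBranches),
              nrow(object@branchPairs)))
  tab <- table(fusedNodes(object@fused)$provenance)
  cat("  fusion:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

#' End-to-end file-based registration run
#'
#' Thin wrapper used by the command-line interface: loads the two graphs
#' (SWC or JSON, by extension), runs [registerVessels()], and writes the
#' fused graph (JSON with provenance), the correspondence TSV and the
#' branch pairing report next to \code{out}.
#'
#' @param referencePath,sensedPath input graph files (.swc or .json).
#' @param out output path for the fused JSON graph; the correspondence and
#'   branch report TSVs take the same stem.
#' @param config a [runConfig()].
#' @param quiet suppress the run log.
#' @return invisibly, the [VesselRegistration-class].
#' @export
runRegister <- function(referencePath, sensedPath, out,
                        config = runConfig(), quiet = FALSE) {
  log <- function(...) if (!quiet) message(format(Sys.time(),
                                                  "%Y-%m-%d %H:%M:%S"),
                                           " INFO ", sprintf(...))
  for (p in c(referencePath, sensedPath))
    if (!file.exists(p)) stop("input file not found: ", p)
  loadGraph <- function(p) {
    if (grepl("\\.swc$", p, ignore.case = TRUE)) readSWC(p)
    else readGraphJSON(p, dropIsolated = TRUE)
  }
  log("parameters: %s",
      paste(sprintf("%s=%s", names(unclass(config)),
                    vapply(unclass(config), format, character(1))),
            collapse = " "))
  ref <- loadGraph(referencePath)
  sen <- loadGraph(sensedPath)
  log("loaded reference %d nodes, sensed %d nodes", nNodes(ref), nNodes(sen))
  reg <- registerVessels(ref, sen, config)
  log("salient pairs: %d; branch pairs: %d", nrow(reg@salientPairs),
      nrow(reg@branchPairs))
  stem <- sub("\\.[^.]*$", "", out)
  writeFusedJSON(reg@fused, out)
  exportCorrespondence(reg@fused, paste0(stem, "_correspondence.tsv"))
  exportBranchPairs(list(pairs = reg@branchPairs),
                    paste0(stem, "_branches.tsv"))
  log("wrote %s", out)
  invisible(reg)
}

#' Evaluate a fused graph against a ground-truth table
#'
#' @param fused a [FusedGraph-class] (or path to a correspondence produced
#'   by [runRegister()], in which case \code{reference} must be supplied as
#'   a path too -- used by the command-line interface).
#' @param truth data.frame (or TSV path) with \code{sensedId} and
#'   \code{refId} columns.
#' @param tol within-tolerance radius; default 2\% of the reference extent.
#' @return the [registrationError()] summary.
#' @export
evaluateRegistration <- function(fused, truth, tol = NULL) {
  if (is.character(truth))
    truth <- utils::read.table(truth, header = TRUE, sep = "\t")
  registrationError(fused, truth, tol)
}
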