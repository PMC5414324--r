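#' @include decomposition.R
NULL

#' Angular difference between two forward directions
#'
#' 2D inputs are CCW angles in degrees; the difference wraps around, so 350
#' and 10 differ by 20.  3D inputs are direction vectors; the difference is
#' the arc cosine of their (clamped) normalized dot product.
#'
#' @param a,b directions: single angles in degrees (2D) or vectors (3D).
#' @return difference in degrees, in [0, 180].
#' @export
angularDifference <- function(a, b) {
  if (length(a) == 1 && length(b) == 1) {
    d <- abs(a - b) %% 360
    min(d, 360 - d)
  } else {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) stop("zero direction vector")
    acos(min(1, max(-1, sum(a * b) / (na * nb)))) * 180 / pi
  }
}

.emptyBranchPairs <- function() {
  data.frame(refBranch = integer(0), sensedBranch = integer(0),
             decidedBy = character(0), directionDiff = numeric(0),
             radiusDiffFrac = numeric(0), tortuosityDiff = numeric(0))
}

#' Match branches between the two decompositions
#'
#' Sequential matching criteria.  Salient-to-salient branches whose two
#' endpoint salient pairs correspond are matched outright
#' (\code{decidedBy = "endpoint"}); when several branches share both
#' endpoints they fall through to the criteria.  All remaining reference
#' branches are processed in ascending id order against the pool of sensed
#' branches anchored at the sensed partner of their anchoring salient point:
#' \enumerate{
#'   \item keep sensed candidates whose forward direction differs by at most
#'     \code{maxAngle} degrees; a single survivor is matched
#'     (\code{"direction"});
#'   \item among survivors, if exactly one has a summed-radius difference
#'     within \code{radiusTol} of the reference value it is matched
#'     (\code{"radius"});
#'   \item otherwise the survivor with the smallest absolute tortuosity
#'     difference is matched (\code{"tortuosity"}; ties to the smaller
#'     sensed id), comparing only relative tortuosity.
#' }
#' Matched sensed branches leave the pool before the next group.  A
#' reference branch with no direction-stage survivor stays unmatched: its
#' information is unique and is routed to fusion rather than force-matched.
#'
#' @param refBranches,sensedBranches branch lists from [decomposeGraph()].
#' @param salientPairs data.frame from [matchSalientPoints()].
#' @param maxAngle maximum allowable angular difference in degrees
#'   (default 60).
#' @param radiusTol allowable fractional summed-radius difference
#'   (default 0.30).
#' @return list with \code{pairs} (data.frame: \code{refBranch},
#'   \code{sensedBranch}, \code{decidedBy}, \code{directionDiff},
#'   \code{radiusDiffFrac}, \code{tortuosityDiff}), \code{unmatchedRef} and
#'   \code{unmatchedSensed} (integer branch ids).
#' @export
matchBranches <- function(refBranches, sensedBranches, salientPairs,
                          maxAngle = 60, radiusTol = 0.30) {
  toSensed <- stats::setNames(salientPairs$sensedId,
                              as.character(salientPairs$refId))
  pairs <- .emptyBranchPairs()
  usedSensed <- logical(length(sensedBranches))
  usedRef <- logical(length(refBranches))
  sensedAnchor <- vapply(sensedBranches, branchAnchor, integer(1))
  sensedTerm <- vapply(sensedBranches, branchTerminal, integer(1))
  sensedKind <- vapply(sensedBranches, branchKind, character(1))

  record <- function(rb, sb, by) {
    dd <- angularDifference(rb@direction, sb@direction)
    rd <- abs(sb@sumRadius - rb@sumRadius) / rb@sumRadius
    td <- abs(sb@tortuosity - rb@tortuosity)
    rbind(pairs, data.frame(refBranch = rb@id, sensedBranch = sb@id,
                            decidedBy = by, directionDiff = dd,
                            radiusDiffFrac = rd, tortuosityDiff = td))
  }

  refIdsOrd <- order(vapply(refBranches, function(b) b@id, integer(1)))

  # stage 0: salient-to-salient branches with uniquely corresponding endpoints
  for (i in refIdsOrd) {
    rb <- refBranches[[i]]
    if (branchKind(rb) != "salient-salient") next
    aS <- toSensed[as.character(branchAnchor(rb))]
    tS <- toSensed[as.character(branchTerminal(rb))]
    if (is.na(aS) || is.na(tS)) next
    cand <- which(!usedSensed & sensedKind == "salient-salient" &
                  sensedAnchor == aS & sensedTerm == tS)
    if (length(cand) == 1) {
      pairs <- record(rb, sensedBranches[[cand]], "endpoint")
      usedSensed[cand] <- TRUE
      usedRef[i] <- TRUE
    }
    # several sharing both endpoints fall through to the criteria below
  }

  # stages 1-3 within anchor-correspondence groups
  for (i in refIdsOrd) {
    if (usedRef[i]) next
    rb <- refBranches[[i]]
    aS <- toSensed[as.character(branchAnchor(rb))]
    if (is.na(aS)) next
    cand <- which(!usedSensed & sensedAnchor == aS)
    if (branchKind(rb) == "salient-salient") {
      tS <- toSensed[as.character(branchTerminal(rb))]
      cand <- cand[sensedKind[cand] == "salient-salient" &
                   sensedTerm[cand] == tS]
    } else {
      cand <- cand[sensedKind[cand] == "salient-leaf"]
    }
    if (!length(cand)) next
    dd <- vapply(cand, function(j)
      angularDifference(rb@direction, sensedBranches[[j]]@direction),
      numeric(1))
    surv <- cand[dd <= maxAngle]
    if (!length(surv)) next                       # unmatched, no forced match
    if (length(surv) == 1) {
      pairs <- record(rb, sensedBranches[[surv]], "direction")
      usedSensed[surv] <- TRUE; usedRef[i] <- TRUE
      next
    }
    rd <- vapply(surv, function(j)
      abs(sensedBranches[[j]]@sumRadius - rb@sumRadius) / rb@sumRadius,
      numeric(1))
    inTol <- surv[rd <= radiusTol]
    if (length(inTol) == 1) {
      pairs <- record(rb, sensedBranches[[inTol]], "radius")
      usedSensed[inTol] <- TRUE; usedRef[i] <- TRUE
      next
    }
    pool <- if (length(inTol) > 1) inTol else surv
    td <- vapply(pool, function(j)
      abs(sensedBranches[[j]]@tortuosity - rb@tortuosity), numeric(1))
    sid <- vapply(pool, function(j) sensedBranches[[j]]@id, integer(1))
    best <- pool[order(td, sid)][1]
    pairs <- record(rb, sensedBranches[[best]], "tortuosity")
    usedSensed[best] <- TRUE; usedRef[i] <- TRUE
  }

  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatchedRef = vapply(refBranches[!usedRef], function(b) b@id,
                             integer(1)),
       unmatchedSensed = vapply(sensedBranches[!usedSensed], function(b) b@id,
                                integer(1)))
}

#' Export the branch pairing report as TSV
#'
#' @param matching result of [matchBranches()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
exportBranchPairs <- function(matching, path) {
  utils::write.table(matching$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
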