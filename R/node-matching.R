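#' @include circuit.R
NULL

#' Linearly scale a sensed voltage sequence onto the reference range
#'
#' The sensed magnitudes \code{Vb} are mapped by the affine transform
#' \code{Vb' = gain * Vb + offset} that sends [min(Vb), max(Vb)] onto
#' [min(Va), max(Va)].  Matching operates on magnitudes of the complex
#' integrated voltages; the argument stays a diagnostic channel.
#'
#' @param Vb sensed magnitudes (nonempty).
#' @param Va reference magnitudes (nonempty).
#' @return list with \code{gain}, \code{offset} and the \code{scaled}
#'   sequence.
#' @examples
#' scaleSequence(c(2, 4), c(1, 5))  # gain 2, offset -3
#' @export
scaleSequence <- function(Vb, Va) {
  stopifnot(length(Vb) > 0, length(Va) > 0)
  rb <- range(Vb); ra <- range(Va)
  if (diff(rb) == 0) stop("degenerate sensed sequence: zero range")
  gain <- diff(ra) / diff(rb)
  offset <- ra[1] - gain * rb[1]
  list(gain = gain, offset = offset, scaled = gain * Vb + offset)
}

#' Match branch nodes through scaled voltage sequences
#'
#' For each sensed node i (voltage \code{VbScaled[i]}), a leading reference
#' node j is searched inside a window centered on i's proportional position
#' along the reference branch, of total width \code{wFrac} of the reference
#' length (minimum 3 nodes).  j brackets the sensed voltage:
#' \code{Va[j] <= VbScaled[i] < Va[j+1]} for increasing reference sequences,
#' with the inequalities flipped for decreasing ones (the direction is
#' detected from the reference endpoints).  The fractional position between
#' the bracket ends,
#' \code{dV1 = (VbScaled[i] - Va[j]) / (Va[j+1] - Va[j])} and
#' \code{dV2 = 1 - dV1}, picks the base node: j when dV1 <= dV2, else j+1,
#' with the voltage difference \code{min(dV1, dV2) <= 0.5}.  When no window
#' position brackets the value the match clamps to the window's
#' nearest-by-value node with difference 0 and a flag.
#'
#' @param Va reference magnitudes, oriented from the anchoring salient
#'   point.
#' @param VbScaled scaled sensed magnitudes, same orientation.
#' @param wFrac search window as a fraction of the reference branch length
#'   (default 0.20).
#' @return data.frame with one row per sensed node: \code{i},
#'   \code{leadingNode}, \code{deltaV}, \code{baseNode}, \code{clamped}.
#' @export
matchNodes <- function(Va, VbScaled, wFrac = 0.20) {
  nA <- length(Va); nB <- length(VbScaled)
  stopifnot(nA > 0, nB > 0)
  decreasing <- Va[1] > Va[nA]
  width <- max(3L, ceiling(wFrac * nA))
  half <- width %/% 2L
  out <- data.frame(i = seq_len(nB), leadingNode = NA_integer_,
                    deltaV = NA_real_, baseNode = NA_integer_,
                    clamped = FALSE)
  for (i in seq_len(nB)) {
    center <- if (nB == 1) 1L else 1L + round((i - 1) * (nA - 1) / (nB - 1))
    win <- max(1L, center - half):min(nA, center + half)
    v <- VbScaled[i]
    js <- win[win <= nA - 1L]
    bracket <- if (decreasing) {
      js[Va[js] >= v & v > Va[js + 1L]]
    } else {
      js[Va[js] <= v & v < Va[js + 1L]]
    }
    if (length(bracket)) {
      j <- bracket[order(abs(bracket - center), bracket)][1]
      dV1 <- (v - Va[j]) / (Va[j + 1L] - Va[j])
      dV2 <- 1 - dV1
      out$leadingNode[i] <- j
      out$deltaV[i] <- min(dV1, dV2)
      out$baseNode[i] <- if (dV1 <= dV2) j else j + 1L
    } else {
      j <- win[order(abs(Va[win] - v), win)][1]
      out$leadingNode[i] <- j
      out$deltaV[i] <- 0
      out$baseNode[i] <- j
      out$clamped[i] <- TRUE
    }
  }
  out
}

#' Export a per-branch node match table as TSV
#'
#' @param matches data.frame from [matchNodes()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
exportNodeMatches <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
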