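# Greedy enhancer peak calling, distance-based peak clustering and the
# spatial-resolution summary.

#' Call non-overlapping enhancer peaks from a probability track
#'
#' All bins with probability >= \code{threshold} are sorted by descending
#' probability (ties: lower genomic coordinate first) and expanded by
#' \code{flank} bins on each side — an 1100-bp window at the defaults. Going
#' down the sorted list, any window overlapping an already accepted window is
#' discarded. Windows are clipped at chromosome ends, so only summits within
#' \code{flank} bins of an end yield a region narrower than
#' \code{(2*flank+1) * binSize} bp.
#'
#' @param prob a \linkS4class{ProbabilityTrack}
#' @param threshold minimum summit probability (default 0.5)
#' @param flank expansion in bins per side (default 5)
#' @return GRanges of peaks sorted by descending summit probability, with
#'   metadata \code{summit_prob}, \code{summit0} (0-based bp of the summit
#'   bin center) and \code{summit_bin} (global bin index)
#' @export
callPeaks <- function(prob, threshold = 0.5, flank = 5L) {
  gb <- prob@bins
  p <- prob@pEnhancer
  cand <- which(p >= threshold)
  emptyPeaks <- function() {
    gr <- GRanges(seqlengths = seqlengths(gb))
    mcols(gr)$summit_prob <- numeric(0)
    mcols(gr)$summit0 <- integer(0)
    mcols(gr)$summit_bin <- integer(0)
    gr
  }
  if (length(cand) == 0L) return(emptyPeaks())
  cand <- cand[order(-p[cand], cand)]

  nb <- chromNBins(gb)
  off <- binOffsets(gb)
  chromIdx <- rep(seq_along(nb), nb)
  firstBin <- (off + 1L)[chromIdx]
  lastBin <- (off + nb)[chromIdx]

  occupied <- logical(nBins(gb))
  keep <- integer(0)
  lo <- hi <- integer(0)
  for (b in cand) {
    wlo <- max(b - flank, firstBin[b])
    whi <- min(b + flank, lastBin[b])
    if (!any(occupied[wlo:whi])) {
      occupied[wlo:whi] <- TRUE
      keep <- c(keep, b)
      lo <- c(lo, wlo)
      hi <- c(hi, whi)
    }
  }
  s0 <- binStart0(gb)
  chrom <- binChrom(gb)
  startBp <- s0[lo]
  endBp <- pmin(s0[hi] + gb@binSize, gb@seqlengths[chrom[hi]])
  out <- GRanges(chrom[keep], IRanges(startBp + 1L, endBp),
                 seqlengths = seqlengths(gb))
  mcols(out)$summit_prob <- p[keep]
  mcols(out)$summit0 <- s0[keep] + gb@binSize %/% 2L
  mcols(out)$summit_bin <- keep
  out
}

#' Cluster enhancer peaks by distance
#'
#' Single-linkage merging of peaks whose edge-to-edge distance is at most
#' \code{maxGap} bp (default 12.5 kb), reflecting the distance criterion used
#' for super-enhancer-like clusters. Clusters of a single peak are returned
#' separately as singletons.
#'
#' @param peaks GRanges of non-overlapping peaks
#' @param maxGap maximum edge-to-edge gap within a cluster (bp)
#' @return list with GRanges \code{clusters} (>= 2 members, metadata
#'   \code{n_peaks}) and \code{singletons}
#' @export
clusterPeaks <- function(peaks, maxGap = 12500L) {
  merged <- reduce(sort(peaks), min.gapwidth = maxGap + 1L, with.revmap = TRUE)
  n <- lengths(mcols(merged)$revmap)
  mcols(merged)$revmap <- NULL
  mcols(merged)$n_peaks <- n
  list(clusters = merged[n >= 2L], singletons = merged[n == 1L])
}

#' Median distance from peak centers to accessible chromatin
#'
#' For every peak, the distance from its center (summit if present) to the
#' nearest reference point of the open-chromatin set — peak summits when a
#' \code{summit0} metadata column is present, otherwise interval boundaries.
#' Peaks farther than \code{maxDist} (default 1 kb) are excluded; the median
#' of the remaining distances is returned.
#'
#' @param peaks GRanges of predicted enhancer peaks (optional metadata
#'   \code{summit0}: 0-based center)
#' @param openRegions GRanges of accessible regions (optional metadata
#'   \code{summit0})
#' @param maxDist exclusion distance in bp (default 1000)
#' @return median distance in bp, or \code{NA_real_} (with a warning) when
#'   every peak is excluded
#' @export
spatialResolution <- function(peaks, openRegions, maxDist = 1000L) {
  stopifnot(length(peaks) > 0L, length(openRegions) > 0L)
  center0 <- if (!is.null(mcols(peaks)$summit0)) mcols(peaks)$summit0
             else start(peaks) - 1L + width(peaks) %/% 2L
  if (!is.null(mcols(openRegions)$summit0)) {
    refChrom <- as.character(seqnames(openRegions))
    refPos <- mcols(openRegions)$summit0
  } else {
    refChrom <- rep(as.character(seqnames(openRegions)), 2L)
    refPos <- c(start(openRegions) - 1L, end(openRegions))
  }
  chrom <- as.character(seqnames(peaks))
  d <- vapply(seq_along(peaks), function(i) {
    same <- refChrom == chrom[i]
    if (!any(same)) return(Inf)
    min(abs(refPos[same] - center0[i]))
  }, numeric(1))
  d <- d[d <= maxDist]
  if (length(d) == 0L) {
    warning("all peaks are farther than maxDist from an accessible region")
    return(NA_real_)
  }
  median(d)
}
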