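# Bin grid arithmetic and read counting.
#
# All external coordinates are 0-based half-open; GRanges objects (1-based,
# closed) are converted at the boundary. Bin i of a chromosome covers
# [i * binSize, (i + 1) * binSize) clipped at the chromosome end.

chromNBins <- function(gb) {
  nb <- as.integer(ceiling(gb@seqlengths / gb@binSize))
  names(nb) <- names(gb@seqlengths)
  nb
}

# global index of the first bin of each chromosome, minus one
binOffsets <- function(gb) {
  nb <- chromNBins(gb)
  off <- cumsum(c(0L, nb[-length(nb)]))
  names(off) <- names(nb)
  off
}

# chromosome of every global bin index
binChrom <- function(gb) {
  rep(names(gb@seqlengths), chromNBins(gb))
}

# 0-based start of every global bin index
binStart0 <- function(gb) {
  nb <- chromNBins(gb)
  unlist(lapply(nb, function(n) (seq_len(n) - 1L) * gb@binSize),
         use.names = FALSE)
}

# global bin index for 0-based positions; NA for chromosomes not in the grid
globalBin <- function(gb, chrom, pos0) {
  off <- binOffsets(gb)
  idx <- off[as.character(chrom)] + pos0 %/% gb@binSize + 1L
  unname(idx)
}

#' Bin grid as a GRanges
#'
#' @param gb a \linkS4class{GenomeBins}
#' @return GRanges with one range per bin, in global bin order
#' @export
binRanges <- function(gb) {
  s0 <- binStart0(gb)
  chrom <- binChrom(gb)
  e0 <- pmin(s0 + gb@binSize, gb@seqlengths[chrom])
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1L, e0),
                         seqlengths = gb@seqlengths)
}

sameBins <- function(a, b) {
  identical(a@binSize, b@binSize) && identical(a@seqlengths, b@seqlengths)
}

stopifDifferentBins <- function(a, b) {
  if (!sameBins(a@bins, b@bins))
    stop("tracks are on different bin grids (bin size or chromosomes differ)")
}

#' Count aligned reads per genomic bin
#'
#' Each read is assigned to exactly one bin: the bin containing its 5'-most
#' aligned position (alignment start on the forward strand, alignment end on
#' the reverse strand; unstranded ranges use their start). Reads on
#' chromosomes absent from the grid are dropped with a message. In
#' \code{fragment} mode properly paired reads are counted once per fragment
#' (first mate only) instead of once per mate.
#'
#' @param reads a BAM/SAM file path, a \code{GRanges} of read alignments, or a
#'   data.frame with columns \code{chrom} and \code{pos} (0-based 5' ends)
#' @param bins a \linkS4class{GenomeBins}
#' @param mark track label for the result
#' @param fragment count paired reads once per fragment
#' @return a \linkS4class{BinnedTrack} of raw counts
#' @examples
#' gb <- genomeBins(c(chr1 = 1000), binSize = 100)
#' reads <- data.frame(chrom = "chr1", pos = c(705, 710, 799))
#' trackValues(binCounts(reads, gb, "H3K27ac"))[8]  # all three land in bin 8
#' @export
binCounts <- function(reads, bins, mark = "input", fragment = FALSE) {
  if (is.character(reads)) {
    reads <- readAlignmentRanges(reads, fragment = fragment)
  }
  if (is(reads, "GRanges")) {
    str <- as.character(strand(reads))
    pos0 <- ifelse(str == "-", end(reads) - 1L, start(reads) - 1L)
    df <- data.frame(chrom = as.character(seqnames(reads)), pos = pos0)
  } else if (is.data.frame(reads)) {
    df <- data.frame(chrom = as.character(reads$chrom), pos = reads$pos)
  } else {
    stop("reads must be a file path, GRanges or data.frame(chrom, pos)")
  }
  n <- nBins(bins)
  if (nrow(df) == 0L)
    return(binnedTrack(bins, mark, numeric(n)))
  keep <- df$chrom %in% names(bins@seqlengths)
  if (!any(keep))
    stop("no overlap: none of the read chromosomes (",
         paste(unique(df$chrom), collapse = ", "),
         ") are present in the bin grid")
  if (any(!keep))
    message(sum(!keep), " read(s) on chromosomes absent from the grid dropped")
  df <- df[keep, , drop = FALSE]
  idx <- globalBin(bins, df$chrom, df$pos)
  binnedTrack(bins, mark, tabulate(idx, nbins = n))
}

# BAM/SAM -> GRanges of alignments (SAM converted on the fly)
readAlignmentRanges <- function(path, fragment = FALSE) {
  if (!file.exists(path)) stop("unreadable alignment source: ", path)
  if (!requireNamespace("GenomicAlignments", quietly = TRUE) ||
      !requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading alignment files requires GenomicAlignments and Rsamtools")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  flag <- if (fragment) {
    Rsamtools::scanBamFlag(isPaired = TRUE, isFirstMateRead = TRUE)
  } else {
    Rsamtools::scanBamFlag()
  }
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flag))
  GenomicRanges::granges(ga)
}
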