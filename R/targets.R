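# Linking differential enhancer regions to target genes: expression
# normalization, TAD-constrained correlation, topology classes, and the
# nearest-gene baseline.

#' Variance-stabilizing normalization of expression counts
#'
#' Default (\code{method = "log"}): median-of-ratios size factors followed by
#' log2(x + 1) — a monotone per-gene transform whose output variance is
#' approximately independent of the mean. \code{method = "vst"} delegates to
#' \code{DESeq2::varianceStabilizingTransformation} when DESeq2 is installed.
#' All-zero gene rows are retained as zeros.
#'
#' @param counts non-negative integer matrix, genes x samples (>= 2 samples)
#' @param method \code{"log"} (default) or \code{"vst"}
#' @return numeric matrix of the same shape
#' @export
normalizeExpression <- function(counts, method = c("log", "vst")) {
  method <- match.arg(method)
  stopifnot(ncol(counts) >= 2L, all(counts >= 0))
  if (method == "vst") {
    if (!requireNamespace("DESeq2", quietly = TRUE))
      stop("method = 'vst' requires the DESeq2 package")
    m <- as.matrix(counts)
    storage.mode(m) <- "integer"
    return(DESeq2::varianceStabilizingTransformation(m, blind = TRUE))
  }
  sf <- sizeFactors(counts)
  log2(sweep(as.matrix(counts), 2L, sf, "/") + 1)
}

# median-of-ratios size factors; falls back to library-size ratios when no
# gene is expressed in every sample
sizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (any(use)) {
    sf <- apply(counts[use, , drop = FALSE], 2L, function(cnt)
      median(exp(log(cnt) - logGeo[use])))
  } else {
    ls <- colSums(counts)
    sf <- ls / mean(ls)
  }
  sf
}

#' Per-sample probabilities of differential regions
#'
#' Extracts, for each differential region, its peak-bin ("summit") enhancer
#' probability in every sample — or the mean probability over the region's
#' bins with \code{aggregate = "mean"}.
#'
#' @param regions GRanges from \code{\link{buildRegions}} (metadata
#'   \code{peak_bin})
#' @param pm the \linkS4class{ProbabilityMatrix} the regions were called from
#' @param aggregate \code{"summit"} (default) or \code{"mean"}
#' @return numeric matrix, regions x samples
#' @export
regionProbMatrix <- function(regions, pm, aggregate = c("summit", "mean")) {
  aggregate <- match.arg(aggregate)
  if (aggregate == "summit") {
    out <- pm@A[mcols(regions)$peak_bin, , drop = FALSE]
  } else {
    br <- binRanges(pm@bins)
    fo <- findOverlaps(regions, br)
    out <- t(vapply(seq_along(regions), function(i) {
      colMeans(pm@A[subjectHits(fo)[queryHits(fo) == i], , drop = FALSE])
    }, numeric(ncol(pm@A))))
  }
  rownames(out) <- regionIds(regions)
  out
}

regionIds <- function(regions) {
  sprintf("%s:%d-%d", as.character(seqnames(regions)),
          start(regions) - 1L, end(regions))
}

#' Link differential enhancers to target genes within TADs
#'
#' For every (region, gene) pair sharing at least one TAD — region judged by
#' its peak position, gene by its TSS — the Pearson correlation between the
#' region's per-sample probabilities and the gene's normalized expression is
#' computed across samples, and pairs with r >= \code{rMin} are emitted as
#' regulatory units. Negative correlations are never emitted; zero-variance
#' vectors are skipped with a warning. TADs may overlap; a pair supported by
#' several TADs is reported once, with the first supporting TAD.
#'
#' @param regions GRanges of differential regions (metadata \code{peak0},
#'   \code{pattern})
#' @param regionProbs regions x samples matrix (see
#'   \code{\link{regionProbMatrix}})
#' @param expr normalized expression matrix, genes x samples, with the same
#'   sample columns as \code{regionProbs}
#' @param tss GRanges of TSS positions with \code{gene_id} metadata
#' @param tads GRanges of TADs (optional \code{tad_id} metadata)
#' @param rMin minimum Pearson correlation (default 0.9)
#' @return data.frame of regulatory units: \code{region}, \code{gene_id},
#'   \code{tad}, \code{r}, plus region coordinates and pattern
#' @export
linkTargets <- function(regions, regionProbs, expr, tss, tads, rMin = 0.9) {
  stopifnot(ncol(regionProbs) >= 3L)
  if (!identical(colnames(regionProbs), colnames(expr)))
    stop("sample columns of regionProbs and expr must match")
  if (length(regions) == 0L)
    return(emptyUnits())
  tadIds <- if (!is.null(mcols(tads)$tad_id)) as.character(mcols(tads)$tad_id)
            else sprintf("tad_%d", seq_along(tads))
  peakPt <- GRanges(seqnames(regions),
                    IRanges(mcols(regions)$peak0 + 1L, width = 1L))
  tssPt <- GRanges(seqnames(tss), IRanges(start(tss), width = 1L))
  regHits <- findOverlaps(peakPt, tads)
  geneHits <- findOverlaps(tssPt, tads)
  geneIds <- as.character(mcols(tss)$gene_id)

  units <- list()
  skipped <- 0L
  for (t in unique(subjectHits(regHits))) {
    ri <- queryHits(regHits)[subjectHits(regHits) == t]
    gi <- queryHits(geneHits)[subjectHits(geneHits) == t]
    gi <- gi[geneIds[gi] %in% rownames(expr)]
    if (length(gi) == 0L) next
    for (i in ri) {
      pv <- regionProbs[i, ]
      if (var(pv) == 0) { skipped <- skipped + length(gi); next }
      for (g in gi) {
        ev <- expr[geneIds[g], ]
        if (var(ev) == 0) { skipped <- skipped + 1L; next }
        r <- cor(pv, ev)
        if (r >= rMin) {
          key <- paste(i, geneIds[g], sep = "\r")
          if (is.null(units[[key]]))
            units[[key]] <- data.frame(region = regionIds(regions)[i],
                                       gene_id = geneIds[g],
                                       tad = tadIds[t], r = r,
                                       chrom = as.character(seqnames(regions))[i],
                                       start0 = start(regions)[i] - 1L,
                                       end0 = end(regions)[i],
                                       pattern = mcols(regions)$pattern[i])
        }
      }
    }
  }
  if (skipped > 0L)
    warning(skipped, " pair(s) skipped: zero-variance probability or expression")
  if (length(units) == 0L) return(emptyUnits())
  out <- do.call(rbind, unname(units))
  rownames(out) <- NULL
  out[order(out$chrom, out$start0, out$gene_id), , drop = FALSE]
}

emptyUnits <- function() {
  data.frame(region = character(0), gene_id = character(0), tad = character(0),
             r = numeric(0), chrom = character(0), start0 = integer(0),
             end0 = integer(0), pattern = character(0))
}

#' Classify the enhancer-gene topology of regulatory units
#'
#' Flags each unit as many:1 (its gene is linked by >= 2 regions) and/or
#' 1:many (its region is linked to >= 2 genes); the primary label is
#' resolved region-first (1:many before many:1), with 1:1 for units whose
#' region and gene each appear exactly once.
#'
#' @param units data.frame from \code{\link{linkTargets}}
#' @return the units with added columns \code{many_to_one},
#'   \code{one_to_many}, \code{topology}
#' @export
classifyTopology <- function(units) {
  if (nrow(units) == 0L) {
    units$many_to_one <- logical(0)
    units$one_to_many <- logical(0)
    units$topology <- character(0)
    return(units)
  }
  geneN <- table(units$gene_id)
  regN <- table(units$region)
  units$many_to_one <- as.vector(geneN[units$gene_id] >= 2L)
  units$one_to_many <- as.vector(regN[units$region] >= 2L)
  units$topology <- ifelse(units$one_to_many, "1:many",
                           ifelse(units$many_to_one, "many:1", "1:1"))
  units
}

#' Nearest-gene baseline assignment
#'
#' Pairs each region with the gene whose TSS is closest to the region's peak
#' (ties: lower TSS coordinate), ignoring TADs and expression. Used to
#' contrast correlation-based target assignment with the naive rule.
#'
#' @param regions GRanges of differential regions (metadata \code{peak0})
#' @param tss GRanges of TSS positions with \code{gene_id}
#' @return data.frame: \code{region}, \code{gene_id}, \code{distance}
#' @export
nearestGeneBaseline <- function(regions, tss) {
  stopifnot(length(tss) > 0L)
  geneIds <- as.character(mcols(tss)$gene_id)
  tssChrom <- as.character(seqnames(tss))
  tssPos0 <- start(tss) - 1L
  peak0 <- mcols(regions)$peak0
  chrom <- as.character(seqnames(regions))
  res <- lapply(seq_along(regions), function(i) {
    same <- which(tssChrom == chrom[i])
    if (length(same) == 0L)
      return(data.frame(region = regionIds(regions)[i],
                        gene_id = NA_character_, distance = NA_real_))
    d <- abs(tssPos0[same] - peak0[i])
    best <- same[d == min(d)]
    best <- best[which.min(tssPos0[best])]
    data.frame(region = regionIds(regions)[i], gene_id = geneIds[best],
               distance = abs(tssPos0[best] - peak0[i]))
  })
  do.call(rbind, res)
}
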