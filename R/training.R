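# Curation of labeled training regions and assembly of the two class-
# stratified training sets.
#
# Labeled regions are GRanges with metadata columns `label` (one of
# enhancer / active_promoter / inactive_promoter / intragenic / intergenic)
# and `center0` (the 0-based bp position whose bin anchors the feature
# window).

TRAINING_COMPOSITION <- list(
  # active-vs-inactive classifier: emulates genome composition
  classifier1 = c(enhancer = 0.10, active_promoter = 0.05,
                  inactive_promoter = 0.05, intragenic = 0.10,
                  intergenic = 0.70),
  # enhancer-vs-active-promoter classifier
  classifier2 = c(enhancer = 2 / 3, active_promoter = 1 / 3)
)

TRAINING_N_DEFAULT <- c(classifier1 = 1000L, classifier2 = 150L)

POSITIVE_LABELS <- list(
  classifier1 = c("enhancer", "active_promoter"),
  classifier2 = "enhancer"
)

# run code under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# largest-remainder rounding of nTotal into integer class counts
allocateCounts <- function(frac, nTotal) {
  raw <- frac * nTotal
  base <- floor(raw)
  k <- nTotal - sum(base)
  if (k > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(k)]] <- base[ord[seq_len(k)]] + 1
    message("class counts rounded by largest remainder to sum to ", nTotal)
  }
  stats::setNames(as.integer(base), names(frac))
}

#' Re-center candidate enhancers on accessibility peaks
#'
#' Keeps only candidates that overlap at least one accessibility (DNase/ATAC)
#' peak and re-centers each retained candidate, preserving its width, on the
#' midpoint of its best-overlapping peak (ties broken towards the leftmost
#' peak). Candidates without any overlap are discarded.
#'
#' @param candidates GRanges of putative enhancers
#' @param peaks GRanges of accessibility peaks
#' @return GRanges of curated enhancers with metadata \code{label} =
#'   "enhancer" and \code{center0} (0-based midpoint of the chosen peak)
#' @export
curateEnhancers <- function(candidates, peaks) {
  if (length(candidates) == 0L) {
    warning("empty candidate enhancer set")
    return(emptyLabeled())
  }
  fo <- findOverlaps(candidates, peaks)
  if (length(fo) == 0L) {
    warning("no candidate enhancer overlaps any accessibility peak")
    return(emptyLabeled())
  }
  ovl <- width(pintersect(candidates[queryHits(fo)], peaks[subjectHits(fo)]))
  pstart <- start(peaks)[subjectHits(fo)]
  # best peak per candidate: max overlap, then leftmost peak start
  ord <- order(queryHits(fo), -ovl, pstart)
  first <- !duplicated(queryHits(fo)[ord])
  qh <- queryHits(fo)[ord][first]
  sh <- subjectHits(fo)[ord][first]
  pk <- peaks[sh]
  center0 <- start(pk) - 1L + width(pk) %/% 2L
  w <- width(candidates[qh])
  out <- GRanges(seqnames(candidates[qh]),
                 IRanges(center0 - w %/% 2L + 1L, width = w))
  mcols(out)$label <- "enhancer"
  mcols(out)$center0 <- center0
  out
}

emptyLabeled <- function() {
  gr <- GRanges()
  mcols(gr)$label <- character(0)
  mcols(gr)$center0 <- integer(0)
  gr
}

#' Label promoters active or inactive from expression and accessibility
#'
#' A promoter is the bin (of width \code{binSize}) containing a gene's TSS.
#' It is labeled active when the gene's FPKM exceeds 2 in every sample and
#' the bin overlaps an accessibility peak; inactive when FPKM is 0 in every
#' sample. Genes with any sample's FPKM in (0, 2] are excluded from both
#' classes, as are active-expression genes whose TSS bin lacks an
#' accessibility peak.
#'
#' @param tss GRanges of TSS positions with a \code{gene_id} metadata column
#' @param fpkm numeric matrix, genes x samples, rownames = gene ids
#' @param peaks GRanges of accessibility peaks
#' @param binSize promoter bin width in bp (default 100)
#' @param fpkmActive active cutoff (FPKM strictly greater; default 2)
#' @return GRanges of promoter bins with \code{label}, \code{gene_id} and
#'   \code{center0} metadata
#' @export
labelPromoters <- function(tss, fpkm, peaks, binSize = 100L, fpkmActive = 2) {
  ids <- as.character(mcols(tss)$gene_id)
  known <- ids %in% rownames(fpkm)
  if (any(!known)) {
    warning(sum(!known), " TSS gene id(s) missing from the expression table; skipped")
    tss <- tss[known]
    ids <- ids[known]
  }
  if (length(tss) == 0L) return(emptyLabeled())
  fm <- fpkm[ids, , drop = FALSE]
  active_expr <- apply(fm > fpkmActive, 1L, all)
  inactive_expr <- apply(fm == 0, 1L, all)

  pos0 <- start(tss) - 1L
  bstart0 <- (pos0 %/% binSize) * binSize
  bin <- GRanges(seqnames(tss), IRanges(bstart0 + 1L, width = binSize))
  hasPeak <- overlapsAny(bin, peaks)

  lab <- rep(NA_character_, length(tss))
  lab[active_expr & hasPeak] <- "active_promoter"
  lab[inactive_expr] <- "inactive_promoter"
  keep <- !is.na(lab)
  out <- bin[keep]
  mcols(out)$label <- lab[keep]
  mcols(out)$gene_id <- ids[keep]
  mcols(out)$center0 <- bstart0[keep] + binSize %/% 2L
  out
}

#' Sample intragenic and intergenic background bins
#'
#' Draws random bins inside gene bodies (intragenic) and outside genes
#' (intergenic), excluding any bin within \code{margin} bp of an already
#' labeled element to avoid label leakage.
#'
#' @param genes GRanges of gene bodies
#' @param labeled GRanges of labeled elements (enhancers, promoters)
#' @param bins a \linkS4class{GenomeBins}
#' @param nIntragenic,nIntergenic numbers of bins to draw
#' @param margin exclusion distance around labeled elements (bp)
#' @param seed RNG seed
#' @return GRanges of background bins with \code{label} and \code{center0}
#' @export
sampleBackgroundBins <- function(genes, labeled, bins, nIntragenic,
                                 nIntergenic, margin = 1000L, seed = 1L) {
  br <- binRanges(bins)
  inGene <- overlapsAny(br, genes)
  nearLabel <- overlapsAny(br, labeled + margin)
  intraIdx <- which(inGene & !nearLabel)
  interIdx <- which(!inGene & !nearLabel)
  if (length(intraIdx) < nIntragenic)
    stop("not enough intragenic bins available (", length(intraIdx), ")")
  if (length(interIdx) < nIntergenic)
    stop("not enough intergenic bins available (", length(interIdx), ")")
  pick <- withSeed(seed, list(
    intra = sample(intraIdx, nIntragenic),
    inter = sample(interIdx, nIntergenic)))
  out <- br[c(pick$intra, pick$inter)]
  mcols(out)$label <- rep(c("intragenic", "intergenic"),
                          c(nIntragenic, nIntergenic))
  mcols(out)$center0 <- start(out) - 1L + width(out) %/% 2L
  out
}

#' Assemble a class-stratified training set
#'
#' Draws, without replacement and reproducibly by seed, a training sample
#' with the fixed class composition of the requested classifier:
#' classifier 1 uses 10% enhancers, 5% active promoters, 5% inactive
#' promoters, 10% intragenic and 70% intergenic regions (default 1000
#' regions); classifier 2 uses 2/3 enhancers and 1/3 active promoters
#' (default 150 regions). Non-integer class quotas are rounded by largest
#' remainder.
#'
#' @param pool GRanges of labeled regions (metadata \code{label})
#' @param task \code{"classifier1"} or \code{"classifier2"}
#' @param nTotal total regions (defaults: 1000 / 150)
#' @param seed RNG seed
#' @return GRanges subset of \code{pool} with a logical \code{positive}
#'   metadata column (classifier 1: enhancers + active promoters;
#'   classifier 2: enhancers)
#' @export
assembleTrainingSet <- function(pool, task = c("classifier1", "classifier2"),
                                nTotal = NULL, seed = 1L) {
  task <- match.arg(task)
  if (is.null(nTotal)) nTotal <- TRAINING_N_DEFAULT[[task]]
  frac <- TRAINING_COMPOSITION[[task]]
  counts <- allocateCounts(frac, nTotal)
  lab <- as.character(mcols(pool)$label)
  idx <- withSeed(seed, {
    unlist(lapply(names(counts), function(cl) {
      avail <- which(lab == cl)
      if (length(avail) < counts[[cl]])
        stop(sprintf("insufficient pool for class '%s': need %d, have %d",
                     cl, counts[[cl]], length(avail)))
      sample(avail, counts[[cl]])
    }))
  })
  out <- pool[idx]
  mcols(out)$positive <- lab[idx] %in% POSITIVE_LABELS[[task]]
  out
}

#' FPKM from raw counts (synthetic-data helper)
#'
#' @param counts integer matrix, genes x samples
#' @param lengths gene lengths in bp (recycled by name or position)
#' @return FPKM matrix
#' @export
fpkmFromCounts <- function(counts, lengths) {
  libSize <- colSums(counts)
  t(t(counts / (lengths / 1e3)) / (libSize / 1e6))
}
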