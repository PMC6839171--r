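#' @importFrom GenomeInfoDb seqlengths seqnames
#' @importFrom GenomicRanges GRanges start end width strand mcols findOverlaps
#'   pintersect reduce seqnames resize distance
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors queryHits subjectHits mcols "mcols<-" DataFrame
NULL

#' Total number of bins in a grid
#' @param x a GenomeBins (or an object carrying one)
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname nBins
#' @export
setMethod("nBins", "GenomeBins", function(x) sum(chromNBins(x)))

#' @rdname nBins
#' @export
setMethod("nBins", "BinnedTrack", function(x) nBins(x@bins))

#' Bin width in bp
#' @param x a GenomeBins, BinnedTrack or FeatureSpec
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname binSize
#' @export
setMethod("binSize", "GenomeBins", function(x) x@binSize)

#' @rdname binSize
#' @export
setMethod("binSize", "BinnedTrack", function(x) x@bins@binSize)

#' @rdname binSize
#' @export
setMethod("binSize", "FeatureSpec", function(x) x@binSize)

#' @export
#' @describeIn GenomeBins-class chromosome lengths
setMethod("seqlengths", "GenomeBins", function(x) x@seqlengths)

#' Per-bin values of a track
#' @param x a BinnedTrack or ProbabilityTrack
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname trackValues
#' @export
setMethod("trackValues", "BinnedTrack", function(x) x@values)

#' Track label (which histone mark or derived track)
#' @param x a BinnedTrack or QuantileReference
#' @export
setGeneric("trackMark", function(x) standardGeneric("trackMark"))

#' @rdname trackMark
#' @export
setMethod("trackMark", "BinnedTrack", function(x) x@mark)

#' @rdname trackMark
#' @export
setMethod("trackMark", "QuantileReference", function(x) x@mark)

#' Joint per-bin enhancer probability (classifier 1 x classifier 2)
#' @param x a ProbabilityTrack
#' @export
setGeneric("probEnhancer", function(x) standardGeneric("probEnhancer"))

#' @rdname probEnhancer
#' @export
setMethod("probEnhancer", "ProbabilityTrack", function(x) x@pEnhancer)

#' Per-bin probability of being an active region (classifier 1)
#' @param x a ProbabilityTrack
#' @export
setGeneric("probActive", function(x) standardGeneric("probActive"))

#' @rdname probActive
#' @export
setMethod("probActive", "ProbabilityTrack", function(x) x@pActive)

#' Per-bin empirical p-values of a condition-pair permutation test
#' @param x a PairTest
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname pValues
#' @export
setMethod("pValues", "PairTest", function(x) x@p)

setMethod("show", "GenomeBins", function(object) {
  cat(sprintf("GenomeBins: %d chromosome(s), bin size %d bp, %d bins\n",
              length(object@seqlengths), object@binSize, nBins(object)))
})

setMethod("show", "BinnedTrack", function(object) {
  v <- object@values
  cat(sprintf("BinnedTrack '%s': %d bins (%d bp), range [%.3g, %.3g]\n",
              object@mark, length(v), object@bins@binSize, min(v), max(v)))
})

setMethod("show", "EnhancerModel", function(object) {
  fs <- object@featureSpec
  cat(sprintf(paste0("EnhancerModel: two probability forests of %d trees; ",
                     "N = %d flanking bins (%d + %d features)\n"),
              object@nTrees, fs@nFlank, 2L * fs@nFlank + 1L,
              4L * (2L * fs@nFlank + 1L)))
  cat(sprintf("  quantile references: %s\n",
              paste(names(object@quantileRefs), collapse = ", ")))
})

setMethod("show", "ProbabilityTrack", function(object) {
  cat(sprintf("ProbabilityTrack: %d bins, %d with P(enhancer) >= 0.5\n",
              nBins(object@bins), sum(object@pEnhancer >= 0.5)))
})

setMethod("show", "ProbabilityMatrix", function(object) {
  cat(sprintf("ProbabilityMatrix: %d bins x %d samples, conditions: %s\n",
              nrow(object@A), ncol(object@A),
              paste(object@conditions, collapse = ", ")))
})

setMethod("show", "PairTest", function(object) {
  cat(sprintf("PairTest %s vs %s (w0 = %g): %d bins, min p = %.3g\n",
              object@pair[1], object@pair[2], object@w0,
              length(object@p), min(object@p)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d chromosome(s), %d x %d design, ",
                     "%d enhancers / %d active / %d inactive promoters, seed %d\n"),
              length(object@seqlengths), object@nConditions,
              object@nReplicates, object@nEnhancers, object@nActiveProm,
              object@nInactiveProm, object@seed))
})
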