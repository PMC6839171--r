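#' @import methods
#' @importFrom stats approx cor median quantile rbinom rnbinom rpois runif var
#' @importFrom utils packageVersion read.table write.table
NULL

HM_MARKS <- c("H3K27ac", "H3K4me1", "H3K4me3")
TRACK_MARKS <- c(HM_MARKS, "input", "ratio")
REGION_LABELS <- c("enhancer", "active_promoter", "inactive_promoter",
                   "intragenic", "intergenic")

#' GenomeBins: a fixed-width binning of a genome
#'
#' Partitions every chromosome into adjacent non-overlapping bins of
#' \code{binSize} bp (default 100). The last bin of a chromosome is clipped at
#' the chromosome end, so a chromosome of length L has \code{ceiling(L /
#' binSize)} bins. Bins are indexed globally (1-based, chromosomes in the
#' order of \code{seqlengths}); all coordinates handed to and returned by the
#' package are 0-based half-open unless they live in a \code{GRanges}.
#'
#' @slot seqlengths named integer vector of chromosome lengths in bp
#' @slot binSize bin width in bp
#' @export
setClass("GenomeBins",
         slots = c(seqlengths = "integer", binSize = "integer"))

setValidity("GenomeBins", function(object) {
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize <= 0L)
    return("binSize must be a single positive integer")
  if (length(object@seqlengths) == 0L)
    return("seqlengths must be non-empty")
  if (is.null(names(object@seqlengths)) || anyDuplicated(names(object@seqlengths)))
    return("seqlengths must have unique chromosome names")
  if (any(object@seqlengths <= 0L))
    return("chromosome lengths must be positive")
  TRUE
})

#' @param seqlengths named vector of chromosome lengths (bp)
#' @param binSize bin width in bp
#' @rdname GenomeBins-class
#' @examples
#' gb <- genomeBins(c(chr1 = 1e6, chr2 = 5e5))
#' nBins(gb)
#' @export
genomeBins <- function(seqlengths, binSize = 100L) {
  sl <- as.integer(seqlengths)
  names(sl) <- names(seqlengths)
  new("GenomeBins", seqlengths = sl, binSize = as.integer(binSize))
}

#' BinnedTrack: one real value per genomic bin
#'
#' Carries a per-bin signal (raw read counts, input-normalized log-ratios,
#' quantile-normalized values, ...) for a single histone mark or derived
#' track, over a \linkS4class{GenomeBins} grid.
#'
#' @slot bins the bin grid
#' @slot mark one of H3K27ac, H3K4me1, H3K4me3, input, ratio
#' @slot values numeric vector, one entry per bin (global bin order)
#' @export
setClass("BinnedTrack",
         slots = c(bins = "GenomeBins", mark = "character",
                   values = "numeric"))

setValidity("BinnedTrack", function(object) {
  if (!(object@mark %in% TRACK_MARKS))
    return(sprintf("mark must be one of: %s", paste(TRACK_MARKS, collapse = ", ")))
  if (length(object@values) != nBins(object@bins))
    return(sprintf("values has length %d but the grid has %d bins",
                   length(object@values), nBins(object@bins)))
  TRUE
})

#' @param bins a \linkS4class{GenomeBins}
#' @param mark track label
#' @param values numeric vector of per-bin values
#' @rdname BinnedTrack-class
#' @export
binnedTrack <- function(bins, mark, values) {
  new("BinnedTrack", bins = bins, mark = mark, values = as.numeric(values))
}

#' QuantileReference: a stored target distribution for quantile normalization
#'
#' A sorted (optionally subsampled) snapshot of the per-bin value distribution
#' of a training track; prediction-time tracks are mapped onto it by rank so
#' that features seen at prediction time follow the distribution the forests
#' were trained on.
#'
#' @slot mark which track the reference describes
#' @slot sortedValues ascending numeric values
#' @export
setClass("QuantileReference",
         slots = c(mark = "character", sortedValues = "numeric"))

setValidity("QuantileReference", function(object) {
  if (length(object@sortedValues) == 0L)
    return("sortedValues must be non-empty")
  if (is.unsorted(object@sortedValues))
    return("sortedValues must be non-decreasing")
  TRUE
})

#' FeatureSpec: geometry of the classifier feature window
#'
#' Each 100-bp bin is described by the track values at the bin itself plus
#' \code{nFlank} (N) bins on either side, i.e. a (2N+1)-bin window of
#' (2N+1) * binSize bp. Classifier 1 (active vs inactive) uses H3K27ac only:
#' 2N+1 features. Classifier 2 (enhancer vs active promoter) uses H3K27ac,
#' H3K4me1, H3K4me3 and the me1/me3 ratio: 4*(2N+1) features. At the default
#' N = 5 this gives 11 and 44 features over an 1100-bp window.
#'
#' @slot nFlank number of flanking bins per side (N, default 5)
#' @slot binSize bin width in bp
#' @export
setClass("FeatureSpec",
         slots = c(nFlank = "integer", binSize = "integer"))

setValidity("FeatureSpec", function(object) {
  if (object@nFlank < 0L) return("nFlank must be >= 0")
  if (object@binSize <= 0L) return("binSize must be > 0")
  TRUE
})

#' @param nFlank flanking bins per side
#' @param binSize bin width in bp
#' @rdname FeatureSpec-class
#' @export
featureSpec <- function(nFlank = 5L, binSize = 100L) {
  new("FeatureSpec", nFlank = as.integer(nFlank), binSize = as.integer(binSize))
}

#' EnhancerModel: the trained two-tier classifier bundle
#'
#' Holds the two probability forests (active vs inactive; enhancer vs active
#' promoter given active), the feature geometry, the per-mark quantile
#' references and the me1/me3 shift constants captured at training time, so
#' that prediction-time normalization reproduces training-time normalization
#' exactly.
#'
#' @slot forestActive ranger probability forest, classifier 1
#' @slot forestEnhVsProm ranger probability forest, classifier 2
#' @slot nTrees trees per forest (M, default 100)
#' @slot featureSpec a \linkS4class{FeatureSpec}
#' @slot quantileRefs named list of \linkS4class{QuantileReference}, one per HM
#' @slot shifts named numeric: training-time minima of the input-normalized
#'   H3K4me1 and H3K4me3 tracks (subtracted before the ratio)
#' @slot provenance list: seed, training composition, package version,
#'   forest hyperparameters
#' @export
setClass("EnhancerModel",
         slots = c(forestActive = "ANY", forestEnhVsProm = "ANY",
                   nTrees = "integer", featureSpec = "FeatureSpec",
                   quantileRefs = "list", shifts = "numeric",
                   provenance = "list"))

setValidity("EnhancerModel", function(object) {
  if (object@nTrees < 1L) return("nTrees must be >= 1")
  if (!all(HM_MARKS %in% names(object@quantileRefs)))
    return("quantileRefs must cover H3K27ac, H3K4me1 and H3K4me3")
  if (!all(c("H3K4me1", "H3K4me3") %in% names(object@shifts)))
    return("shifts must name H3K4me1 and H3K4me3")
  TRUE
})

#' ProbabilityTrack: per-bin enhancer probabilities
#'
#' The three per-bin probabilities of the two-tier model:
#' \code{pEnhancer = pActive * pEnhGivenActive} holds exactly, elementwise.
#'
#' @slot bins the bin grid
#' @slot pActive P(bin active), classifier 1
#' @slot pEnhGivenActive P(bin enhancer | active), classifier 2
#' @slot pEnhancer joint enhancer probability
#' @export
setClass("ProbabilityTrack",
         slots = c(bins = "GenomeBins", pActive = "numeric",
                   pEnhGivenActive = "numeric", pEnhancer = "numeric"))

setValidity("ProbabilityTrack", function(object) {
  n <- nBins(object@bins)
  if (length(object@pActive) != n || length(object@pEnhGivenActive) != n ||
      length(object@pEnhancer) != n)
    return("probability vectors must have one entry per bin")
  rng <- range(c(object@pActive, object@pEnhGivenActive, object@pEnhancer))
  if (rng[1] < 0 || rng[2] > 1)
    return("probabilities must lie in [0, 1]")
  if (any(abs(object@pEnhancer - object@pActive * object@pEnhGivenActive) > 1e-12))
    return("pEnhancer must equal pActive * pEnhGivenActive elementwise")
  TRUE
})

#' @param bins a \linkS4class{GenomeBins}
#' @param pActive,pEnhGivenActive per-bin probabilities from the two forests
#' @rdname ProbabilityTrack-class
#' @export
probabilityTrack <- function(bins, pActive, pEnhGivenActive) {
  new("ProbabilityTrack", bins = bins, pActive = as.numeric(pActive),
      pEnhGivenActive = as.numeric(pEnhGivenActive),
      pEnhancer = as.numeric(pActive) * as.numeric(pEnhGivenActive))
}

#' ProbabilityMatrix: bins x samples enhancer probabilities with a design
#'
#' Collects per-sample enhancer probability tracks into the matrix A (rows =
#' bins, columns = samples) together with the sample-to-condition assignment.
#'
#' @slot A numeric matrix in [0,1], bins x samples
#' @slot bins the shared bin grid
#' @slot conditionOf named character: sample -> condition
#' @slot conditions ordered unique condition labels
#' @export
setClass("ProbabilityMatrix",
         slots = c(A = "matrix", bins = "GenomeBins",
                   conditionOf = "character", conditions = "character"))

setValidity("ProbabilityMatrix", function(object) {
  if (nrow(object@A) != nBins(object@bins))
    return("A must have one row per bin")
  if (is.null(colnames(object@A)) ||
      !identical(sort(colnames(object@A)), sort(names(object@conditionOf))))
    return("conditionOf must name every sample column of A")
  if (!all(object@conditionOf %in% object@conditions))
    return("every sample's condition must appear in conditions")
  if (length(object@conditions) < 2L)
    return("at least two conditions are required")
  rng <- range(object@A)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    return("entries of A must lie in [0, 1]")
  TRUE
})

#' @param tracks named list of \linkS4class{ProbabilityTrack} (or numeric
#'   vectors), one per sample
#' @param conditions character vector: condition of each sample, in the order
#'   of \code{tracks}
#' @param bins required when \code{tracks} are bare numeric vectors
#' @rdname ProbabilityMatrix-class
#' @export
probabilityMatrix <- function(tracks, conditions, bins = NULL) {
  stopifnot(length(tracks) == length(conditions))
  if (is.null(names(tracks)))
    names(tracks) <- sprintf("sample%d", seq_along(tracks))
  vals <- lapply(tracks, function(tr) {
    if (is(tr, "ProbabilityTrack")) {
      if (is.null(bins)) bins <<- tr@bins
      tr@pEnhancer
    } else as.numeric(tr)
  })
  if (is.null(bins))
    stop("bins must be supplied when tracks are plain numeric vectors")
  A <- do.call(cbind, vals)
  colnames(A) <- names(tracks)
  condOf <- as.character(conditions)
  names(condOf) <- names(tracks)
  new("ProbabilityMatrix", A = A, bins = bins, conditionOf = condOf,
      conditions = unique(condOf))
}

#' PairTest: permutation test result for one condition pair
#'
#' The statistic is one-sided, so both orderings of the pair are tested:
#' \code{p} holds the per-bin p-values of the forward test (C1 more active
#' than C2), \code{pRev} of the reverse.
#'
#' @slot pair the two condition labels (C1, C2)
#' @slot w0 minimum group difference tested under H0: |mu1 - mu2| <= w0
#' @slot Ttrue observed per-bin statistic, forward direction
#' @slot muDiff per-bin mu(C1) - mu(C2), used for the pattern sign
#' @slot p per-bin empirical p-values, forward (C1 > C2)
#' @slot pRev per-bin empirical p-values, reverse (C2 > C1)
#' @slot nNull size of the permutation null sample
#' @export
setClass("PairTest",
         slots = c(pair = "character", w0 = "numeric", Ttrue = "numeric",
                   muDiff = "numeric", p = "numeric", pRev = "numeric",
                   nNull = "integer"))

setValidity("PairTest", function(object) {
  if (length(object@pair) != 2L) return("pair must have two condition labels")
  if (length(object@p) != length(object@Ttrue) ||
      length(object@pRev) != length(object@Ttrue))
    return("p, pRev and Ttrue must be parallel")
  lo <- 1 / (1 + object@nNull)
  if (any(object@p < lo - 1e-12 | object@p > 1 + 1e-12) ||
      any(object@pRev < lo - 1e-12 | object@pRev > 1 + 1e-12))
    return("p-values must lie in [1/(1+nNull), 1]")
  TRUE
})

#' SimConfig: parameters of the synthetic-data generator
#'
#' Describes the synthetic genome: chromosome lengths, design (conditions x
#' replicates), numbers of planted elements, and the count model. Enhancers
#' are planted as two Gaussian-profile H3K4me1/H3K27ac read bumps at
#' +/- flankOffset bp around an accessible (signal-free) center; active
#' promoters as a central H3K4me3 + H3K27ac bump; background is
#' negative-binomial noise at \code{backgroundRate} reads/bin.
#'
#' @slot seqlengths named integer chromosome lengths
#' @slot binSize bin width (bp)
#' @slot nConditions,nReplicates design
#' @slot nEnhancers,nActiveProm,nInactiveProm planted element counts (genome-wide)
#' @slot sharedFrac fraction of enhancers active in all conditions; the rest
#'   are specific to one condition (round-robin)
#' @slot backgroundRate mean background reads per bin
#' @slot strength enrichment multiplier of planted signal over background
#' @slot flankOffset distance (bp) of the HM bumps from the element center
#' @slot signalSd Gaussian sd (bp) of each bump
#' @slot dispersion negative-binomial dispersion of background counts
#'   (variance = mu + dispersion * mu^2)
#' @slot minSpacing minimum distance between planted centers (bp)
#' @slot tadWidth width of the tiled TADs (bp)
#' @slot seed RNG seed: identical configs give identical output
#' @export
setClass("SimConfig",
         slots = c(seqlengths = "integer", binSize = "integer",
                   nConditions = "integer", nReplicates = "integer",
                   nEnhancers = "integer", nActiveProm = "integer",
                   nInactiveProm = "integer", sharedFrac = "numeric",
                   backgroundRate = "numeric", strength = "numeric",
                   flankOffset = "integer", signalSd = "numeric",
                   dispersion = "numeric", minSpacing = "integer",
                   tadWidth = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (any(c(object@nEnhancers, object@nActiveProm, object@nInactiveProm) < 0L))
    return("element counts must be >= 0")
  if (object@nConditions < 1L || object@nReplicates < 1L)
    return("need >= 1 condition and >= 1 replicate")
  if (object@strength <= 0) return("strength must be > 0")
  if (object@backgroundRate <= 0) return("backgroundRate must be > 0")
  if (object@sharedFrac < 0 || object@sharedFrac > 1)
    return("sharedFrac must be in [0, 1]")
  TRUE
})
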