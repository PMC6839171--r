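# Two-tier random-forest enhancer classifier.
#
# Classifier 1 (active vs inactive region) sees H3K27ac only; classifier 2
# (enhancer vs active promoter, given active) sees H3K27ac, H3K4me1, H3K4me3
# and the me1/me3 ratio. Each bin is described by a (2N+1)-bin window of
# track values, and the final per-bin enhancer probability is the product
#   P(enhancer) = P(active) * P(enhancer | active).

#' @importFrom ranger ranger
NULL

MARKS_C1 <- "H3K27ac"
MARKS_C2 <- c("H3K27ac", "H3K4me1", "H3K4me3", "ratio")

featureMarks <- function(task) {
  switch(task, classifier1 = MARKS_C1, classifier2 = MARKS_C2,
         stop("unknown task: ", task))
}

#' Build the classifier feature matrix
#'
#' One row per center bin: the concatenated values of each required track at
#' bins center-N ... center+N (mark-major, fixed order H3K27ac, H3K4me1,
#' H3K4me3, ratio for classifier 2). Window positions that fall off the
#' center's chromosome are zero-padded and the row is flagged in the
#' \code{"clipped"} attribute.
#'
#' @param tracks named list of \linkS4class{BinnedTrack}s on one grid
#' @param centers global bin indices of the window centers
#' @param spec a \linkS4class{FeatureSpec}
#' @param task \code{"classifier1"} or \code{"classifier2"}
#' @return numeric matrix, length(centers) x (marks * (2N+1)), with a logical
#'   \code{"clipped"} attribute marking zero-padded rows
#' @export
buildFeatures <- function(tracks, centers, spec = featureSpec(),
                          task = c("classifier1", "classifier2")) {
  task <- match.arg(task)
  marks <- featureMarks(task)
  missing <- setdiff(marks, names(tracks))
  if (length(missing) > 0L)
    stop("missing track(s) for ", task, ": ", paste(missing, collapse = ", "))
  gb <- tracks[[marks[1]]]@bins
  nb <- chromNBins(gb)
  chromIdx <- rep(seq_along(nb), nb)
  total <- sum(nb)
  if (length(centers) > 0L && (min(centers) < 1L || max(centers) > total))
    stop("center bin indices out of range")
  N <- spec@nFlank
  offs <- seq.int(-N, N)
  ncolPerMark <- length(offs)
  out <- matrix(0, nrow = length(centers), ncol = length(marks) * ncolPerMark)
  clipped <- logical(length(centers))
  centerChrom <- chromIdx[centers]
  for (m in seq_along(marks)) {
    v <- tracks[[marks[m]]]@values
    if (length(v) != total) stop("tracks are on different bin grids")
    for (k in seq_along(offs)) {
      idx <- centers + offs[k]
      ok <- idx >= 1L & idx <= total
      ok[ok] <- chromIdx[idx[ok]] == centerChrom[ok]
      col <- numeric(length(centers))
      col[ok] <- v[idx[ok]]
      clipped <- clipped | !ok
      out[, (m - 1L) * ncolPerMark + k] <- col
    }
  }
  colnames(out) <- as.vector(outer(sprintf("f%02d", seq_along(offs)),
                                   marks, function(a, b) paste(b, a, sep = "_")))
  attr(out, "clipped") <- clipped
  out
}

centerBins <- function(regions, gb) {
  globalBin(gb, as.character(seqnames(regions)), mcols(regions)$center0)
}

fitForest <- function(x, y, nTrees, seed) {
  if (length(unique(y)) < 2L)
    stop("degenerate training set: only one class present")
  ranger::ranger(x = x, y = factor(y, levels = c(FALSE, TRUE)),
                 num.trees = nTrees, probability = TRUE,
                 seed = seed, num.threads = 1L)
}

forestProb <- function(forest, x) {
  pr <- stats::predict(forest, data = x, num.threads = 1L)$predictions
  unname(pr[, "TRUE"])
}

#' Train the two-tier enhancer model
#'
#' Fits classifier 1 (active vs inactive) on H3K27ac window features of the
#' first training set and classifier 2 (enhancer vs active promoter) on the
#' four-track features of the second, and captures the quantile references
#' and me1/me3 shift constants of the training tracks so prediction-time
#' normalization reproduces training-time normalization.
#'
#' @param tracks named list of input-normalized \linkS4class{BinnedTrack}s
#'   (\code{H3K27ac}, \code{H3K4me1}, \code{H3K4me3})
#' @param trainSet1,trainSet2 labeled GRanges from
#'   \code{\link{assembleTrainingSet}} (metadata \code{positive},
#'   \code{center0})
#' @param nFlank flanking bins per side (N, default 5)
#' @param nTrees trees per forest (M, default 100)
#' @param seed RNG seed (forests and provenance)
#' @return an \linkS4class{EnhancerModel}
#' @export
trainEnhancerModel <- function(tracks, trainSet1, trainSet2, nFlank = 5L,
                               nTrees = 100L, seed = 1L) {
  stopifnot(all(HM_MARKS %in% names(tracks)))
  gb <- tracks$H3K27ac@bins
  spec <- featureSpec(nFlank = nFlank, binSize = gb@binSize)
  shifts <- trackShifts(tracks$H3K4me1, tracks$H3K4me3)
  tracks$ratio <- ratioTrack(tracks$H3K4me1, tracks$H3K4me3, shifts = shifts)

  x1 <- buildFeatures(tracks, centerBins(trainSet1, gb), spec, "classifier1")
  x2 <- buildFeatures(tracks, centerBins(trainSet2, gb), spec, "classifier2")
  f1 <- fitForest(x1, mcols(trainSet1)$positive, nTrees, seed)
  f2 <- fitForest(x2, mcols(trainSet2)$positive, nTrees, seed + 1L)

  refs <- lapply(tracks[HM_MARKS], quantileReference)
  new("EnhancerModel", forestActive = f1, forestEnhVsProm = f2,
      nTrees = as.integer(nTrees), featureSpec = spec, quantileRefs = refs,
      shifts = shifts,
      provenance = list(seed = seed,
                        n_train = c(classifier1 = length(trainSet1),
                                    classifier2 = length(trainSet2)),
                        mtry = c(f1$mtry, f2$mtry),
                        package_version = as.character(packageVersion("enhanceRF"))))
}

#' Genome-wide enhancer probabilities from a trained model
#'
#' Input-normalized tracks are quantile normalized to the model's stored
#' training references, the me1/me3 ratio is rebuilt with the stored
#' training-time shifts, window features are assembled for every bin, and
#' both forests are applied. Per bin,
#' \code{pEnhancer = pActive * pEnhGivenActive}.
#'
#' @param model an \linkS4class{EnhancerModel}
#' @param tracks named list of input-normalized \linkS4class{BinnedTrack}s
#'   (\code{H3K27ac}, \code{H3K4me1}, \code{H3K4me3})
#' @param quantileNorm apply quantile normalization to the training
#'   references (default TRUE; FALSE is only useful for studying the effect
#'   of normalization)
#' @return a \linkS4class{ProbabilityTrack}
#' @export
predictEnhancers <- function(model, tracks, quantileNorm = TRUE) {
  missing <- setdiff(HM_MARKS, names(tracks))
  if (length(missing) > 0L)
    stop("missing track(s): ", paste(missing, collapse = ", "))
  gb <- tracks$H3K27ac@bins
  if (quantileNorm) {
    tracks <- lapply(stats::setNames(HM_MARKS, HM_MARKS), function(mk)
      quantileNormalizeTrack(tracks[[mk]], model@quantileRefs[[mk]]))
  } else {
    tracks <- tracks[HM_MARKS]
  }
  tracks$ratio <- ratioTrack(tracks$H3K4me1, tracks$H3K4me3,
                             shifts = model@shifts)
  centers <- seq_len(nBins(gb))
  x1 <- buildFeatures(tracks, centers, model@featureSpec, "classifier1")
  x2 <- buildFeatures(tracks, centers, model@featureSpec, "classifier2")
  probabilityTrack(gb,
                   pActive = forestProb(model@forestActive, x1),
                   pEnhGivenActive = forestProb(model@forestEnhVsProm, x2))
}

#' Single combined forest baseline
#'
#' Trains one probability forest that separates enhancers from everything
#' else (active/inactive promoters, intra-/intergenic background) in a single
#' step, on the full four-track feature set. This is the natural baseline for
#' quantifying what the two-tier design buys, particularly the suppression of
#' false enhancer probability at active promoters.
#'
#' @inheritParams trainEnhancerModel
#' @param trainSet genome-composition training set (classifier-1 style), with
#'   enhancers as the positive class
#' @return list with the fitted forest, feature spec, quantile references and
#'   shifts (consumed by \code{\link{predictCombinedForest}})
#' @export
trainCombinedForest <- function(tracks, trainSet, nFlank = 5L, nTrees = 100L,
                                seed = 1L) {
  gb <- tracks$H3K27ac@bins
  spec <- featureSpec(nFlank = nFlank, binSize = gb@binSize)
  shifts <- trackShifts(tracks$H3K4me1, tracks$H3K4me3)
  tracks$ratio <- ratioTrack(tracks$H3K4me1, tracks$H3K4me3, shifts = shifts)
  x <- buildFeatures(tracks, centerBins(trainSet, gb), spec, "classifier2")
  y <- as.character(mcols(trainSet)$label) == "enhancer"
  list(forest = fitForest(x, y, nTrees, seed), featureSpec = spec,
       quantileRefs = lapply(tracks[HM_MARKS], quantileReference),
       shifts = shifts)
}

#' @rdname trainCombinedForest
#' @param fit result of \code{trainCombinedForest}
#' @export
predictCombinedForest <- function(fit, tracks, quantileNorm = TRUE) {
  if (quantileNorm) {
    tracks <- lapply(stats::setNames(HM_MARKS, HM_MARKS), function(mk)
      quantileNormalizeTrack(tracks[[mk]], fit$quantileRefs[[mk]]))
  } else {
    tracks <- tracks[HM_MARKS]
  }
  tracks$ratio <- ratioTrack(tracks$H3K4me1, tracks$H3K4me3,
                             shifts = fit$shifts)
  gb <- tracks$H3K27ac@bins
  x <- buildFeatures(tracks, seq_len(nBins(gb)), fit$featureSpec, "classifier2")
  forestProb(fit$forest, x)
}
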