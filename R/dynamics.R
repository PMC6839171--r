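# Differential enhancer calling: permutation test on the bins x samples
# probability matrix, activity-pattern assignment, and merging of patterned
# bins into differential regions.

#' Weighted two-group test statistic
#'
#' T = (mu1 - mu2 - w0) / S, where S is the pooled standard deviation of the
#' two groups scaled by sqrt(1/n1 + 1/n2). The null hypothesis is
#' |mu1 - mu2| <= w0. When either group has a single member the pooled SD is
#' undefined and S is replaced by a small constant (1e-8); the same
#' replacement is applied when the pooled SD is exactly zero, so that a
#' constant matrix yields identical finite statistics for every bin.
#'
#' @param values numeric vector of per-sample probabilities for one bin
#' @param groups logical or 2-level factor assigning each value to a group
#'   (TRUE / first level = condition 1)
#' @param w0 minimum group difference (default 0.5)
#' @param eps replacement for an undefined or zero pooled SD
#' @return the statistic (single number)
#' @examples
#' testStatistic(c(0.9, 1.0, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE), 0.5)
#' @export
testStatistic <- function(values, groups, w0 = 0.5, eps = 1e-8) {
  if (is.factor(groups)) groups <- groups == levels(groups)[1]
  g1 <- values[groups]
  g2 <- values[!groups]
  if (length(g1) == 0L || length(g2) == 0L)
    stop("both groups must be non-empty")
  rowTstat(matrix(g1, nrow = 1), matrix(g2, nrow = 1), w0, eps)$T
}

# vectorized statistic over all bins; M1, M2 are bins x replicates.
# Returns the forward statistic T = (mu1 - mu2 - w0)/S, the reverse
# statistic Trev = (mu2 - mu1 - w0)/S, and the raw mean difference.
rowTstat <- function(M1, M2, w0, eps = 1e-8) {
  n1 <- ncol(M1)
  n2 <- ncol(M2)
  mu1 <- rowMeans(M1)
  mu2 <- rowMeans(M2)
  if (n1 == 1L || n2 == 1L) {
    S <- rep(eps, length(mu1))
  } else {
    v1 <- pmax(rowSums(M1 * M1) - n1 * mu1 * mu1, 0) / (n1 - 1)
    v2 <- pmax(rowSums(M2 * M2) - n2 * mu2 * mu2, 0) / (n2 - 1)
    S2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2) * (1 / n1 + 1 / n2)
    S <- sqrt(S2)
    S[S == 0] <- eps
  }
  d <- mu1 - mu2
  list(T = (d - w0) / S, Trev = (-d - w0) / S, muDiff = d)
}

#' Permutation test for one condition pair
#'
#' Computes the per-bin statistic between the two conditions, then builds an
#' empirical null by globally shuffling all entries of the pair's submatrix
#' and recomputing the statistic for every bin (\code{rounds} shuffles give
#' rounds x bins null values). The empirical p-value uses add-one counting,
#' p = (1 + #\{null >= T\}) / (1 + nNull), so the smallest attainable p is
#' 1 / (1 + number of bins) at one round. Because the statistic is one-sided,
#' both orderings of the pair are tested against their respective nulls
#' (slots \code{p} and \code{pRev}).
#'
#' @param pm a \linkS4class{ProbabilityMatrix}
#' @param pair character(2): the two condition labels (C1, C2)
#' @param w0 minimum group difference (default 0.5)
#' @param seed RNG seed for the shuffle
#' @param rounds number of global shuffles (default 1)
#' @return a \linkS4class{PairTest}
#' @export
permutationPvalues <- function(pm, pair, w0 = 0.5, seed = 1L, rounds = 1L) {
  stopifnot(length(pair) == 2L, all(pair %in% pm@conditions))
  cols1 <- names(pm@conditionOf)[pm@conditionOf == pair[1]]
  cols2 <- names(pm@conditionOf)[pm@conditionOf == pair[2]]
  if (length(cols1) == 0L || length(cols2) == 0L)
    stop("both conditions need at least one sample")
  nbins <- nrow(pm@A)
  if (nbins < 2L) stop("need at least two bins")
  M <- pm@A[, c(cols1, cols2), drop = FALSE]
  i1 <- seq_along(cols1)
  i2 <- length(cols1) + seq_along(cols2)
  true <- rowTstat(M[, i1, drop = FALSE], M[, i2, drop = FALSE], w0)

  null <- withSeed(seed, {
    res <- lapply(seq_len(rounds), function(r) {
      P <- matrix(sample(M), nrow = nbins)
      rowTstat(P[, i1, drop = FALSE], P[, i2, drop = FALSE], w0)
    })
    list(fwd = unlist(lapply(res, `[[`, "T")),
         rev = unlist(lapply(res, `[[`, "Trev")))
  })
  empiricalP <- function(tTrue, tNull) {
    tNull <- sort(tNull)
    # #(null >= t) = nNull - #(null < t)
    exceed <- length(tNull) - findInterval(tTrue, tNull, left.open = TRUE)
    (1 + exceed) / (1 + length(tNull))
  }
  nNull <- length(null$fwd)
  new("PairTest", pair = as.character(pair), w0 = w0, Ttrue = true$T,
      muDiff = true$muDiff, p = empiricalP(true$T, null$fwd),
      pRev = empiricalP(true$Trev, null$rev), nNull = as.integer(nNull))
}

#' Enumerate the activity-pattern universe
#'
#' For |C| conditions there are choose(|C|, 2) unordered pairs, each assigned
#' one of \{10, 01, 00\}; the uninformative all-00 pattern is excluded,
#' giving 3^choose(|C|,2) - 1 patterns (26 for three conditions).
#'
#' @param nConditions number of conditions (>= 2)
#' @return character vector of pattern strings (pair codes joined by ",")
#' @export
enumeratePatterns <- function(nConditions) {
  if (nConditions < 2L) stop("need at least two conditions")
  nPairs <- choose(nConditions, 2)
  grid <- expand.grid(rep(list(c("00", "10", "01")), nPairs),
                      stringsAsFactors = FALSE)
  pat <- apply(grid, 1L, paste, collapse = ",")
  allZero <- paste(rep("00", nPairs), collapse = ",")
  pat[pat != allZero]
}

# five-bin significance window: TRUE at x iff sig holds at x-2 .. x+2 and all
# five bins lie on x's chromosome (no wrap across chromosome ends)
runFive <- function(sig, chromIdx) {
  n <- length(sig)
  out <- sig
  for (k in c(-2L, -1L, 1L, 2L)) {
    idx <- seq_len(n) + k
    ok <- idx >= 1L & idx <= n
    shifted <- logical(n)
    shifted[ok] <- sig[idx[ok]] & chromIdx[idx[ok]] == chromIdx[ok]
    out <- out & shifted
  }
  out
}

#' Assign per-bin activity patterns from pairwise tests
#'
#' For each condition pair, a bin x gets code 10 when the empirical p-values
#' at bins x-2 ... x+2 are all <= \code{pStar} and mu(C1) > mu(C2); 01 in the
#' opposite direction; 00 otherwise (including whenever one of the five bins
#' falls off the chromosome). Returns the differential bins — those whose
#' joint pattern over all pairs is not all-00 — with a representative
#' p-value (minimum over the pairs in which the bin is significant).
#'
#' @param pairTests list of \linkS4class{PairTest}, one per unordered pair
#' @param bins the shared \linkS4class{GenomeBins}
#' @param pStar significance cutoff on the empirical p-values (default 0.05)
#' @return data.frame with columns \code{bin} (global index), \code{pattern}
#'   (pair codes joined by ","), \code{p} (representative p-value)
#' @export
assignPatterns <- function(pairTests, bins, pStar = 0.05) {
  nb <- chromNBins(bins)
  chromIdx <- rep(seq_along(nb), nb)
  n <- sum(nb)
  codes <- matrix("00", nrow = n, ncol = length(pairTests))
  repP <- matrix(NA_real_, nrow = n, ncol = length(pairTests))
  for (j in seq_along(pairTests)) {
    pt <- pairTests[[j]]
    stopifnot(length(pt@p) == n)
    up <- runFive(pt@p <= pStar, chromIdx) & pt@muDiff > 0
    dn <- runFive(pt@pRev <= pStar, chromIdx) & pt@muDiff < 0
    codes[up, j] <- "10"
    codes[dn, j] <- "01"
    repP[up, j] <- pt@p[up]
    repP[dn, j] <- pt@pRev[dn]
  }
  pattern <- do.call(paste, c(split(codes, col(codes)), sep = ","))
  diffBin <- rowSums(codes != "00") > 0L
  data.frame(bin = which(diffBin), pattern = pattern[diffBin],
             p = apply(repP[diffBin, , drop = FALSE], 1L, min, na.rm = TRUE))
}

#' Merge patterned bins into differential enhancer regions
#'
#' Bins sharing an activity pattern are merged when at most \code{mergeGap}
#' bp apart (edge to edge, same chromosome); each region stores its
#' lowest-p bin as peak. Overlapping regions with different patterns are then
#' combined and labeled with the pattern of the member with the lowest peak
#' p-value.
#'
#' @param diffBins data.frame from \code{\link{assignPatterns}}
#' @param bins the \linkS4class{GenomeBins}
#' @param mergeGap merge distance in bp (default 2000)
#' @return GRanges with metadata \code{pattern}, \code{peak0} (0-based bp of
#'   the peak bin center), \code{peak_bin}, \code{peak_p}
#' @export
buildRegions <- function(diffBins, bins, mergeGap = 2000L) {
  emptyRegions <- function() {
    gr <- GRanges(seqlengths = seqlengths(bins))
    mcols(gr) <- DataFrame(pattern = character(0), peak0 = integer(0),
                           peak_bin = integer(0), peak_p = numeric(0))
    gr
  }
  if (nrow(diffBins) == 0L) return(emptyRegions())
  nb <- chromNBins(bins)
  chromIdx <- rep(seq_along(nb), nb)
  s0 <- binStart0(bins)
  chrom <- binChrom(bins)
  bs <- bins@binSize
  maxStep <- mergeGap %/% bs + 1L  # bin-index step with edge gap <= mergeGap

  pieces <- lapply(split(diffBins, diffBins$pattern), function(df) {
    df <- df[order(df$bin), , drop = FALSE]
    b <- df$bin
    newGrp <- c(TRUE, diff(b) > maxStep | diff(chromIdx[b]) != 0L)
    grp <- cumsum(newGrp)
    do.call(rbind, lapply(split(seq_along(b), grp), function(ii) {
      bb <- b[ii]
      pk <- ii[which.min(df$p[ii])]
      data.frame(chrom = chrom[bb[1]], start0 = s0[bb[1]],
                 end0 = s0[bb[length(bb)]] + bs,
                 pattern = df$pattern[pk], peak_bin = df$bin[pk],
                 peak_p = df$p[pk])
    }))
  })
  reg <- do.call(rbind, pieces)
  gr <- GRanges(reg$chrom, IRanges(reg$start0 + 1L, reg$end0),
                seqlengths = seqlengths(bins))
  mcols(gr)$pattern <- reg$pattern
  mcols(gr)$peak_bin <- reg$peak_bin
  mcols(gr)$peak_p <- reg$peak_p

  # combine overlapping regions of different patterns: lowest peak p wins
  merged <- reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  members <- mcols(merged)$revmap
  win <- vapply(members, function(ii) ii[which.min(mcols(gr)$peak_p[ii])],
                integer(1))
  out <- merged
  mcols(out) <- DataFrame(pattern = mcols(gr)$pattern[win],
                          peak0 = s0[mcols(gr)$peak_bin[win]] + bs %/% 2L,
                          peak_bin = mcols(gr)$peak_bin[win],
                          peak_p = mcols(gr)$peak_p[win])
  sort(out)
}

#' Differential enhancer regions across all condition pairs
#'
#' Runs the permutation test for every unordered condition pair (each with a
#' pair-specific sub-seed derived from \code{seed}), assigns per-bin activity
#' patterns and merges them into differential regions.
#'
#' @param pm a \linkS4class{ProbabilityMatrix}
#' @param w0 minimum group difference (default 0.5)
#' @param pStar empirical p-value cutoff (default 0.05)
#' @param mergeGap region merge distance in bp (default 2000)
#' @param seed RNG seed
#' @param rounds shuffle rounds per pair (default 1)
#' @return list: \code{regions} (GRanges as from \code{\link{buildRegions}}),
#'   \code{pairTests} (named list of \linkS4class{PairTest}), \code{pairs}
#'   (2-row matrix of tested condition pairs)
#' @export
enhancerDynamics <- function(pm, w0 = 0.5, pStar = 0.05, mergeGap = 2000L,
                             seed = 1L, rounds = 1L) {
  pairs <- utils::combn(pm@conditions, 2L)
  pairTests <- lapply(seq_len(ncol(pairs)), function(j)
    permutationPvalues(pm, pairs[, j], w0 = w0, seed = seed + j,
                       rounds = rounds))
  names(pairTests) <- apply(pairs, 2L, paste, collapse = "_vs_")
  diffBins <- assignPatterns(pairTests, pm@bins, pStar = pStar)
  list(regions = buildRegions(diffBins, pm@bins, mergeGap = mergeGap),
       pairTests = pairTests, pairs = pairs)
}
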