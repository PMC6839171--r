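# Shared fixtures. The benchmark pipeline (two independently simulated
# genomes, a model trained on the first and applied to the second) is
# expensive, so it is built once per test run and cached.

.cache <- new.env(parent = emptyenv())

smallBins <- function(len = 1000L, binSize = 100L, chroms = "chr1") {
  genomeBins(stats::setNames(rep(len, length(chroms)), chroms), binSize)
}

makeTrack <- function(values, mark = "H3K27ac", bins = NULL) {
  if (is.null(bins)) bins <- smallBins(len = length(values) * 100L)
  binnedTrack(bins, mark, values)
}

# normalized tracks for one sample of a simulation
normalizedSample <- function(sim, sample) {
  lapply(sim$samples[[sample]], function(tr) inputNormalize(tr, sim$input))
}

# a small, fast simulated genome + model for unit tests (1 chromosome,
# 20 trees); not the benchmark
tinyModelFixture <- function() {
  if (!is.null(.cache$tiny)) return(.cache$tiny)
  cfg <- simConfig(seqlengths = c(chr1 = 4e5), nEnhancers = 30L,
                   nActiveProm = 12L, nInactiveProm = 12L,
                   minSpacing = 4000L, seed = 41L)
  sim <- simulateTracks(cfg)
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(10000, 350000, by = 40000), width = 2000))
  pool <- labelPoolFromTruth(sim, genes, "cond1", nIntragenic = 60L,
                             nIntergenic = 200L, seed = 42L)
  ts1 <- assembleTrainingSet(pool, "classifier1", nTotal = 200L, seed = 43L)
  ts2 <- assembleTrainingSet(pool, "classifier2", nTotal = 30L, seed = 44L)
  model <- trainEnhancerModel(normalizedSample(sim, "cond1_rep1"), ts1, ts2,
                              nTrees = 20L, seed = 45L)
  .cache$tiny <- list(cfg = cfg, sim = sim, pool = pool, model = model,
                      ts1 = ts1, ts2 = ts2)
  .cache$tiny
}

# the benchmark: default 2 x 1 Mb genome, 2 conditions x 2 replicates;
# train on genome A (cond1_rep1), evaluate on genome B
benchmarkPipeline <- function() {
  if (!is.null(.cache$bench)) return(.cache$bench)
  cfgA <- simConfig(seed = 11L)
  cfgB <- simConfig(seed = 22L)
  simA <- simulateTracks(cfgA)
  simB <- simulateTracks(cfgB)
  tadsA <- simulateTads(cfgA)
  exprA <- simulateExpression(simA$truth, tadsA, cfgA)
  genesA <- exprA$genes
  pool <- labelPoolFromTruth(simA, genesA, "cond1", seed = 3L)
  ts1 <- assembleTrainingSet(pool, "classifier1", seed = 4L)
  ts2 <- assembleTrainingSet(pool, "classifier2", seed = 5L)
  trainTracks <- normalizedSample(simA, "cond1_rep1")
  model <- trainEnhancerModel(trainTracks, ts1, ts2, seed = 6L)
  probs <- lapply(names(simB$samples),
                  function(s) predictEnhancers(model, normalizedSample(simB, s)))
  names(probs) <- names(simB$samples)
  pm <- probabilityMatrix(probs, simB$conditions)
  .cache$bench <- list(cfgA = cfgA, cfgB = cfgB, simA = simA, simB = simB,
                       pool = pool, ts1 = ts1, trainTracks = trainTracks,
                       model = model, probs = probs, pm = pm)
  .cache$bench
}

# distance from each planted center to the nearest peak summit (Inf if none
# on the same chromosome)
summitDistances <- function(elements, peaks) {
  summit0 <- S4Vectors::mcols(peaks)$summit0
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  vapply(seq_len(nrow(elements)), function(i) {
    same <- chrom == elements$chrom[i]
    if (!any(same)) return(Inf)
    min(abs(summit0[same] - elements$center0[i]))
  }, numeric(1))
}

# truth subsets
activeEnhancers <- function(truth, condition) {
  truth[truth$kind == "enhancer" & vapply(
    strsplit(truth$active_in, ",", fixed = TRUE),
    function(x) condition %in% x, logical(1)), , drop = FALSE]
}

conditionSpecificEnhancers <- function(truth) {
  truth[truth$kind == "enhancer" & !grepl(",", truth$active_in) &
          truth$active_in != "", , drop = FALSE]
}

# brute-force greedy peak-calling oracle on a single chromosome: candidates
# sorted by (-p, index); a window is kept iff it overlaps no kept window
oraclePeakSummits <- function(p, threshold = 0.5, flank = 5L) {
  cand <- which(p >= threshold)
  cand <- cand[order(-p[cand], cand)]
  n <- length(p)
  keptLo <- integer(0)
  keptHi <- integer(0)
  summits <- integer(0)
  for (b in cand) {
    lo <- max(1L, b - flank)
    hi <- min(n, b + flank)
    if (!any(lo <= keptHi & hi >= keptLo)) {
      keptLo <- c(keptLo, lo)
      keptHi <- c(keptHi, hi)
      summits <- c(summits, b)
    }
  }
  summits
}

# direct evaluation of the weighted statistic, used as the independent oracle
oracleT <- function(g1, g2, w0, eps = 1e-8) {
  n1 <- length(g1)
  n2 <- length(g2)
  S <- if (n1 == 1 || n2 == 1) eps else {
    S2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2) *
      (1 / n1 + 1 / n2)
    if (S2 == 0) eps else sqrt(S2)
  }
  (mean(g1) - mean(g2) - w0) / S
}

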