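test_that("identical configs give identical synthetic data", {
  cfg <- simConfig(seqlengths = c(chr1 = 2e5), nEnhancers = 10L,
                   nActiveProm = 5L, nInactiveProm = 5L, minSpacing = 4000L,
                   seed = 3L)
  s1 <- simulateTracks(cfg)
  s2 <- simulateTracks(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(trackValues(s1$samples$cond1_rep1$H3K27ac),
                   trackValues(s2$samples$cond1_rep1$H3K27ac))
  expect_identical(trackValues(s1$input), trackValues(s2$input))

  e1 <- simulateExpression(s1$truth, simulateTads(cfg), cfg)
  e2 <- simulateExpression(s2$truth, simulateTads(cfg), cfg)
  expect_identical(e1$counts, e2$counts)
})

test_that("an element-free genome is pure background noise", {
  cfg <- simConfig(seqlengths = c(chr1 = 5e5), nEnhancers = 0L,
                   nActiveProm = 0L, nInactiveProm = 0L, seed = 9L)
  sim <- simulateTracks(cfg)
  v <- trackValues(sim$samples$cond1_rep1$H3K27ac)
  # mean within 3 standard errors of the background rate
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - cfg@backgroundRate), 3 * se)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("planted enhancers produce strong local mark enrichment", {
  cfg <- simConfig(seqlengths = c(chr1 = 5e5), nEnhancers = 10L,
                   nActiveProm = 0L, nInactiveProm = 0L, sharedFrac = 1,
                   seed = 5L)
  sim <- simulateTracks(cfg)
  gb <- sim$bins
  v27 <- trackValues(sim$samples$cond1_rep1$H3K27ac)
  vme3 <- trackValues(sim$samples$cond1_rep1$H3K4me3)
  bg <- cfg@backgroundRate
  disp <- cfg@dispersion
  for (i in seq_len(nrow(sim$truth))) {
    b <- enhanceRF:::globalBin(gb, sim$truth$chrom[i], sim$truth$center0[i])
    win <- (b - 5):(b + 5)
    # 11-bin H3K27ac sum: expectation 11*bg under background alone, NB sd
    expSum <- 11 * bg
    sdSum <- sqrt(11 * (bg + disp * bg^2))
    expect_gt(sum(v27[win]), expSum + 5 * sdSum)
    # no H3K4me3 at enhancers: within background fluctuation
    expect_lt(sum(vme3[win]), expSum + 5 * sdSum)
  }
  # the accessible center itself carries less signal than the flanks
  ctr <- enhanceRF:::globalBin(gb, sim$truth$chrom, sim$truth$center0)
  expect_lt(mean(v27[ctr]), mean(c(v27[ctr - 2], v27[ctr + 2])))
})

test_that("planted centers respect the minimum spacing", {
  cfg <- simConfig(seed = 13L)
  truth <- simulateTracks(cfg)$truth
  for (ch in unique(truth$chrom)) {
    ctr <- sort(truth$center0[truth$chrom == ch])
    expect_gte(min(diff(ctr)), 2L * cfg@flankOffset)
  }
  # design annotations are complete
  expect_equal(sum(truth$kind == "enhancer"), cfg@nEnhancers)
  expect_true(all(truth$active_in[truth$kind == "inactive_promoter"] == ""))
})

test_that("expression tracks planted enhancer activity", {
  cfg <- simConfig(seqlengths = c(chr1 = 1e6), nEnhancers = 30L,
                   nActiveProm = 0L, nInactiveProm = 0L, sharedFrac = 0.5,
                   seed = 21L)
  sim <- simulateTracks(cfg)
  tads <- simulateTads(cfg)
  ex <- simulateExpression(sim$truth, tads, cfg, nDecoys = 20L)
  counts <- ex$counts
  cond <- rep(c("cond1", "cond2"), each = 2)

  condMean <- function(g, cd) mean(counts[g, cond == cd])
  for (k in seq_len(nrow(ex$links))) {
    act <- ex$links$active_in[k]
    g <- ex$links$gene_id[k]
    if (act == "cond1") expect_gt(condMean(g, "cond1"), 2 * condMean(g, "cond2"))
    if (act == "cond2") expect_gt(condMean(g, "cond2"), 2 * condMean(g, "cond1"))
  }
  # decoys show no systematic condition effect
  decoys <- grep("^decoy", rownames(counts), value = TRUE)
  lfc <- log2((rowMeans(counts[decoys, cond == "cond1"]) + 1) /
                (rowMeans(counts[decoys, cond == "cond2"]) + 1))
  expect_lt(abs(mean(lfc)), 0.25)

  # every target gene's TSS shares a TAD with its enhancer
  tadOf <- function(chrom, pos0) which(
    as.character(GenomicRanges::seqnames(tads)) == chrom &
      GenomicRanges::start(tads) - 1 <= pos0 & GenomicRanges::end(tads) > pos0)
  for (k in seq_len(nrow(ex$links))) {
    ei <- ex$links$enhancer[k]
    tssRow <- ex$tss[S4Vectors::mcols(ex$tss)$gene_id == ex$links$gene_id[k]]
    expect_equal(
      tadOf(sim$truth$chrom[ei], sim$truth$center0[ei]),
      tadOf(as.character(GenomicRanges::seqnames(tssRow)),
            GenomicRanges::start(tssRow) - 1L))
  }
})

test_that("the labeled pool covers all five classes with usable counts", {
  fx <- tinyModelFixture()
  lab <- S4Vectors::mcols(fx$pool)$label
  expect_setequal(unique(lab),
                  c("enhancer", "active_promoter", "inactive_promoter",
                    "intragenic", "intergenic"))
  # enhancer labels stay within the jitter of a planted active enhancer
  enh <- fx$pool[lab == "enhancer"]
  truth <- activeEnhancers(fx$sim$truth, "cond1")
  d <- vapply(S4Vectors::mcols(enh)$center0, function(c0)
    min(abs(truth$center0 - c0)), numeric(1))
  expect_lte(max(d), 150)
})
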