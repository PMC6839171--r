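library(GenomicRanges)

test_that("enhancer curation recenters on the best-overlapping peak", {
  cand <- GRanges("chr1", IRanges(1001, 1600))          # [1000, 1600)
  peak <- GRanges("chr1", IRanges(1201, 1400))          # [1200, 1400)
  out <- curateEnhancers(cand, peak)
  expect_equal(mcols(out)$center0, 1300)
  expect_equal(width(out), 600)                          # width preserved
  expect_equal(start(out) - 1L, 1000)

  # no overlap -> dropped
  far <- GRanges("chr1", IRanges(9001, 9100))
  out2 <- curateEnhancers(c(cand, far), peak)
  expect_length(out2, 1L)

  # two peaks: larger overlap wins; equal overlap -> leftmost
  peaks <- GRanges("chr1", IRanges(c(1001, 1301), c(1100, 1500)))
  out3 <- curateEnhancers(cand, peaks)
  expect_equal(mcols(out3)$center0, 1400)                # 200-bp overlap wins
  tie <- GRanges("chr1", IRanges(c(1001, 1501), c(1100, 1600)))
  out4 <- curateEnhancers(cand, tie)
  expect_equal(mcols(out4)$center0, 1050)                # leftmost on tie

  expect_warning(res <- curateEnhancers(GRanges(), peak), "empty")
  expect_length(res, 0L)
})

test_that("promoter labeling follows the FPKM and accessibility rules", {
  tss <- GRanges("chr1", IRanges(c(1051, 2051, 3051, 4051), width = 1))
  mcols(tss)$gene_id <- c("gActive", "gSilent", "gWeak", "gClosed")
  fpkm <- rbind(gActive = c(3.0, 4.1), gSilent = c(0, 0), gWeak = c(0.5, 3),
                gClosed = c(5, 6))
  peaks <- GRanges("chr1", IRanges(c(1001, 3001), c(1200, 3200)))

  out <- labelPromoters(tss, fpkm, peaks)
  lab <- stats::setNames(mcols(out)$label, mcols(out)$gene_id)
  expect_equal(unname(lab["gActive"]), "active_promoter")
  expect_equal(unname(lab["gSilent"]), "inactive_promoter")
  expect_false("gWeak" %in% names(lab))    # FPKM in (0, 2] excluded
  expect_false("gClosed" %in% names(lab))  # expressed but no accessibility

  # promoter bin is the 100-bp bin containing the TSS
  expect_equal(width(out), rep(100L, length(out)))
  expect_true(all(start(out) %% 100 == 1))

  # partition: no gene in both classes
  expect_false(any(duplicated(mcols(out)$gene_id)))

  # unknown genes are skipped with a warning
  tss2 <- c(tss, GRanges("chr1", IRanges(5051, width = 1),
                         gene_id = "gUnknown"))
  expect_warning(labelPromoters(tss2, fpkm, peaks), "missing")
})

test_that("training sets have the exact stratified composition", {
  mkPool <- function(ns) {
    labs <- rep(names(ns), ns)
    gr <- GRanges("chr1", IRanges(seq_along(labs) * 2000 + 1, width = 100))
    mcols(gr)$label <- labs
    mcols(gr)$center0 <- start(gr) + 49L
    gr
  }
  pool <- mkPool(c(enhancer = 150, active_promoter = 80,
                   inactive_promoter = 80, intragenic = 150, intergenic = 800))
  ts1 <- assembleTrainingSet(pool, "classifier1", seed = 1L)
  expect_length(ts1, 1000L)
  expect_equal(as.vector(table(mcols(ts1)$label)[
    c("enhancer", "active_promoter", "inactive_promoter", "intragenic",
      "intergenic")]), c(100, 50, 50, 100, 700))
  expect_equal(sum(mcols(ts1)$positive), 150)  # enhancers + active promoters

  ts2 <- assembleTrainingSet(pool, "classifier2", seed = 1L)
  expect_length(ts2, 150L)
  expect_equal(sum(mcols(ts2)$label == "enhancer"), 100)
  expect_equal(sum(mcols(ts2)$label == "active_promoter"), 50)
  expect_equal(sum(mcols(ts2)$positive), 100)

  # reproducible and duplicate-free
  again <- assembleTrainingSet(pool, "classifier1", seed = 1L)
  expect_identical(start(again), start(ts1))
  key <- paste(seqnames(ts1), start(ts1))
  expect_false(any(duplicated(key)))

  # a different seed draws a different sample
  other <- assembleTrainingSet(pool, "classifier1", seed = 2L)
  expect_false(identical(start(other), start(ts1)))

  # deficient pool errors and names the class
  tiny <- mkPool(c(enhancer = 5, active_promoter = 80, inactive_promoter = 80,
                   intragenic = 150, intergenic = 800))
  expect_error(assembleTrainingSet(tiny, "classifier1", seed = 1L),
               "enhancer")

  # non-divisible totals resolved by largest remainder, sum preserved
  expect_message(ts3 <- assembleTrainingSet(pool, "classifier1",
                                            nTotal = 10L, seed = 1L),
                 "largest remainder")
  expect_length(ts3, 10L)
})

test_that("background bins avoid genes and labeled elements as required", {
  gb <- genomeBins(c(chr1 = 100000), binSize = 100)
  genes <- GRanges("chr1", IRanges(c(10001, 50001), width = 10000))
  labeled <- GRanges("chr1", IRanges(30001, 31100))
  mcols(labeled)$label <- "enhancer"
  mcols(labeled)$center0 <- 30550L
  bg <- sampleBackgroundBins(genes, labeled, gb, 20, 50, seed = 1L)
  intra <- bg[mcols(bg)$label == "intragenic"]
  inter <- bg[mcols(bg)$label == "intergenic"]
  expect_length(intra, 20L)
  expect_length(inter, 50L)
  expect_true(all(overlapsAny(intra, genes)))
  expect_false(any(overlapsAny(inter, genes)))
  expect_false(any(overlapsAny(bg, labeled + 1000L)))
})

test_that("FPKM helper scales by gene length and library size", {
  counts <- rbind(g1 = c(100, 200), g2 = c(900, 1800))
  f <- fpkmFromCounts(counts, lengths = c(1000, 2000))
  # g1: 100 / 1 kb / (1000/1e6 M reads) = 1e5
  expect_equal(unname(f["g1", 1]), 1e5)
  expect_equal(f[, 1], f[, 2])  # doubled library, doubled counts
})
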