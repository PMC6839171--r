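library(GenomicRanges)

mkRegions <- function(peak0, chrom = "chr1", pattern = "10") {
  gr <- GRanges(chrom, IRanges(peak0 - 499, peak0 + 500))
  mcols(gr)$pattern <- rep(pattern, length.out = length(gr))
  mcols(gr)$peak0 <- peak0
  mcols(gr)$peak_bin <- NA_integer_
  mcols(gr)$peak_p <- 1e-4
  gr
}

mkTss <- function(pos0, ids, chrom = "chr1") {
  gr <- GRanges(chrom, IRanges(pos0 + 1, width = 1))
  mcols(gr)$gene_id <- ids
  gr
}

test_that("expression normalization stabilizes variance and keeps structure", {
  counts <- rbind(g1 = c(10, 10, 10), g2 = c(100, 100, 100),
                  g3 = c(0, 0, 0), g4 = c(50, 50, 70))
  ne <- normalizeExpression(counts)
  # identical columns stay identical
  expect_equal(ne[, 1], ne[, 2])
  # all-zero rows are retained as zeros
  expect_equal(unname(ne["g3", ]), rep(0, 3))

  # doubling one library changes the column but preserves per-gene ordering
  c2 <- counts
  c2[, 3] <- c2[, 3] * 2
  ne2 <- normalizeExpression(c2)
  expect_equal(order(ne2["g4", ]), order(ne["g4", ]))

  # negative-binomial simulation: after the transform, log(sd) is roughly
  # flat in log(mean) across four decades of expression
  set.seed(42)
  mu <- 10^runif(300, 1, 4)
  sim <- t(vapply(mu, function(m) rnbinom(8, mu = m, size = 10), numeric(8)))
  rownames(sim) <- sprintf("g%d", seq_len(nrow(sim)))
  colnames(sim) <- sprintf("s%d", 1:8)
  nes <- normalizeExpression(sim)
  sds <- apply(nes, 1, sd)
  means <- rowMeans(nes)
  slope <- coef(lm(log(sds) ~ means))[2]
  expect_gt(slope, -0.25)
  expect_lt(slope, 0.25)
})

test_that("targets are linked only within shared TADs at r >= rMin", {
  tads <- GRanges("chr1", IRanges(c(1, 50001), width = 50000))
  mcols(tads)$tad_id <- c("tadA", "tadB")
  regions <- mkRegions(c(10000, 60000))
  probs <- rbind(c(0.9, 0.8, 0.1, 0.0),
                 c(0.1, 0.0, 0.9, 0.8))
  colnames(probs) <- sprintf("s%d", 1:4)
  rownames(probs) <- enhanceRF:::regionIds(regions)
  tss <- mkTss(c(20000, 70000, 75000), c("gA", "gB", "gC"))
  expr <- rbind(gA = probs[1, ] * 10 + 1,       # r = 1 with region 1
                gB = rev(probs[2, ]) * 10,      # anti-correlated with region 2
                gC = probs[2, ] * 5 + rnorm(4, 0, 0.01))
  colnames(expr) <- colnames(probs)

  units <- linkTargets(regions, probs, expr, tss, tads, rMin = 0.9)
  # gA pairs with region 1 in tadA; gC with region 2 in tadB; gB dropped
  expect_setequal(units$gene_id, c("gA", "gC"))
  expect_equal(units$tad[units$gene_id == "gA"], "tadA")
  expect_true(all(units$r >= 0.9))
  # cross-TAD pairs are never tested even when perfectly correlated
  expect_false(any(units$gene_id == "gA" & units$tad == "tadB"))

  # zero-variance vectors are skipped with a warning
  exprZ <- expr
  exprZ["gA", ] <- 5
  expect_warning(uz <- linkTargets(regions, probs, exprZ, tss, tads,
                                   rMin = 0.9), "zero-variance")
  expect_false("gA" %in% uz$gene_id)

  # fewer than three samples is an error
  expect_error(linkTargets(regions, probs[, 1:2], expr[, 1:2], tss, tads))
})

test_that("linking agrees with a brute-force all-pairs oracle", {
  set.seed(17)
  tadW <- 20000
  tads <- GRanges("chr1", IRanges(seq(1, 8 * tadW, by = tadW), width = tadW))
  mcols(tads)$tad_id <- sprintf("t%d", 1:8)
  peak0 <- sort(sample(seq(1000, 8 * tadW - 1000), 12))
  regions <- mkRegions(peak0)
  probs <- matrix(runif(12 * 5), nrow = 12,
                  dimnames = list(enhanceRF:::regionIds(regions),
                                  sprintf("s%d", 1:5)))
  tssPos <- sort(sample(seq(1000, 8 * tadW - 1000), 20))
  tss <- mkTss(tssPos, sprintf("g%02d", 1:20))
  expr <- matrix(runif(20 * 5), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:5)))

  rMin <- 0.5
  units <- linkTargets(regions, probs, expr, tss, tads, rMin = rMin)

  # oracle: enumerate every (region, gene, tad) triple
  want <- character(0)
  for (i in seq_along(regions)) for (g in seq_along(tss)) {
    sameTad <- any(peak0[i] >= start(tads) - 1 & peak0[i] < end(tads) &
                     tssPos[g] >= start(tads) - 1 & tssPos[g] < end(tads))
    if (sameTad && cor(probs[i, ], expr[g, ]) >= rMin)
      want <- c(want, paste(i, rownames(expr)[g]))
  }
  got <- paste(match(units$region, enhanceRF:::regionIds(regions)),
               units$gene_id)
  expect_setequal(got, want)
})

test_that("topology classes reflect region and gene multiplicity", {
  units <- data.frame(
    region = c("r1", "r2", "r3", "r3", "r4", "r5"),
    gene_id = c("g1", "g2", "g2", "g3", "g4", "g4"),
    tad = "t", r = 0.95)
  out <- classifyTopology(units)
  expect_equal(out$topology[out$region == "r1"], "1:1")
  # g2 is hit by r2 and r3 -> many:1; r3 also hits g3 -> 1:many (region-first)
  expect_equal(out$topology[out$region == "r2"], "many:1")
  expect_true(all(out$topology[out$region == "r3"] == "1:many"))
  expect_true(all(out$many_to_one[out$gene_id == "g4"]))

  # flags reconcile with multiplicities on any input
  withMult <- merge(out, as.data.frame(table(gene_id = units$gene_id)))
  expect_equal(withMult$many_to_one, withMult$Freq >= 2)
})

test_that("nearest-gene baseline picks the closest TSS with a tie rule", {
  regions <- mkRegions(10000)
  tss <- mkTss(c(9000, 12000), c("near", "far"))
  nb <- nearestGeneBaseline(regions, tss)
  expect_equal(nb$gene_id, "near")
  expect_equal(nb$distance, 1000)

  tie <- mkTss(c(9000, 11000), c("left", "right"))
  expect_equal(nearestGeneBaseline(regions, tie)$gene_id, "left")

  # the nearest gene is not automatically the regulated gene: a decoy TSS
  # 5 kb away loses to a correlated target 15 kb away under linkTargets
  tads <- GRanges("chr1", IRanges(1, 50000), tad_id = "t1")
  probs <- matrix(c(0.9, 0.85, 0.05, 0.1), nrow = 1,
                  dimnames = list(enhanceRF:::regionIds(regions),
                                  sprintf("s%d", 1:4)))
  genes <- mkTss(c(15000, 25000), c("decoy", "target"))
  expr <- rbind(decoy = c(5, 5.1, 5, 5.1),
                target = c(9, 8.8, 5.2, 5.4))
  colnames(expr) <- colnames(probs)
  expect_equal(nearestGeneBaseline(regions, genes)$gene_id, "decoy")
  units <- linkTargets(regions, probs, expr, genes, tads, rMin = 0.9)
  expect_equal(units$gene_id, "target")
})
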