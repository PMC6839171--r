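smallMatrix <- function(A, conditions, chrom = c(chr1 = nrow(A) * 100)) {
  colnames(A) <- sprintf("s%d", seq_len(ncol(A)))
  probabilityMatrix(asplit(A, 2), conditions, bins = genomeBins(chrom))
}

test_that("the weighted statistic matches direct evaluation", {
  # pooled SD forced to 1: T = (1 - 0 - 0.5) / 1
  a <- 1 / sqrt(2)
  g1 <- c(1 - a, 1 + a)
  g2 <- c(-a, a)
  expect_equal(testStatistic(c(g1, g2), rep(c(TRUE, FALSE), each = 2), 0.5),
               0.5)

  # identical groups at w0 = 0 give exactly 0
  expect_equal(testStatistic(c(0.3, 0.3, 0.3, 0.3),
                             c(TRUE, TRUE, FALSE, FALSE), 0), 0)

  # worked example: S^2 = 0.005
  expect_equal(testStatistic(c(0.9, 1.0, 0.1, 0.2),
                             c(TRUE, TRUE, FALSE, FALSE), 0.5),
               0.3 / sqrt(0.005), tolerance = 1e-12)
  expect_equal(0.3 / sqrt(0.005), 4.2426, tolerance = 1e-4)

  expect_error(testStatistic(c(1, 2), c(TRUE, TRUE), 0.5), "non-empty")

  # enumerated group sizes against the oracle
  set.seed(12)
  for (n1 in 1:4) for (n2 in 1:4) {
    g1 <- runif(n1)
    g2 <- runif(n2)
    expect_equal(testStatistic(c(g1, g2), rep(c(TRUE, FALSE), c(n1, n2)), 0.3),
                 oracleT(g1, g2, 0.3))
  }
})

test_that("empirical p-values respect the counting convention and floor", {
  # one bin far above anything the null can produce -> floor; flat bins -> 1
  set.seed(3)
  n <- 400
  A <- matrix(runif(n * 4, 0, 0.05), ncol = 4)
  A[7, ] <- c(1, 1, 0, 0)
  A[8, ] <- c(0, 0, 1, 1)
  pm <- smallMatrix(A, c("c1", "c1", "c2", "c2"))
  pt <- permutationPvalues(pm, c("c1", "c2"), w0 = 0.5, seed = 1L)
  expect_equal(pt@nNull, n)
  # above every null value -> the floor; below every null value -> exactly 1
  expect_equal(pValues(pt)[7], 1 / (1 + n))
  expect_equal(pValues(pt)[8], 1)
  expect_equal(pt@pRev[8], 1 / (1 + n))

  # constant matrix: every statistic identical, all p = 1 in both directions
  Ac <- matrix(0.4, nrow = 50, ncol = 4)
  pmc <- smallMatrix(Ac, c("c1", "c1", "c2", "c2"))
  ptc <- permutationPvalues(pmc, c("c1", "c2"), w0 = 0, seed = 1L)
  expect_true(all(pValues(ptc) == 1))
  expect_true(all(ptc@pRev == 1))

  # reproducibility by seed
  pt2 <- permutationPvalues(pm, c("c1", "c2"), w0 = 0.5, seed = 1L)
  expect_identical(pValues(pt2), pValues(pt))
  expect_error(permutationPvalues(pm, c("c1", "cX"), w0 = 0.5, seed = 1L))
})

test_that("swapping condition labels swaps the activity patterns exactly", {
  set.seed(21)
  n <- 300
  A <- matrix(runif(n * 4, 0, 0.2), ncol = 4)
  up <- sample(10:(n - 10), 8)
  for (x in up) A[(x - 2):(x + 2), 1:2] <- runif(10, 0.85, 1)
  dn <- sample(setdiff(20:(n - 20), as.vector(outer(up, -7:7, "+"))), 6)
  for (x in dn) A[(x - 2):(x + 2), 3:4] <- runif(10, 0.85, 1)

  pmF <- smallMatrix(A, c("c1", "c1", "c2", "c2"))
  pmR <- smallMatrix(A, c("c2", "c2", "c1", "c1"))
  ptF <- permutationPvalues(pmF, c("c1", "c2"), w0 = 0.5, seed = 5L)
  ptR <- permutationPvalues(pmR, c("c1", "c2"), w0 = 0.5, seed = 5L)
  dbF <- assignPatterns(list(ptF), pmF@bins)
  dbR <- assignPatterns(list(ptR), pmR@bins)
  expect_identical(dbF$bin, dbR$bin)
  expect_identical(dbF$pattern == "10", dbR$pattern == "01")
})

test_that("pattern assignment needs all five bins significant", {
  mkPair <- function(p, pRev, muDiff) {
    new("PairTest", pair = c("c1", "c2"), w0 = 0.5, Ttrue = muDiff,
        muDiff = muDiff, p = p, pRev = pRev, nNull = 1000L)
  }
  n <- 20
  gb <- genomeBins(c(chr1 = n * 100))
  base <- rep(1, n)
  up <- base; up[8:12] <- 0.01
  pt <- mkPair(up, base, rep(0.8, n))
  db <- assignPatterns(list(pt), gb)
  expect_equal(db$bin, 10L)             # only the window center qualifies
  expect_equal(db$pattern, "10")

  # one failing neighbor kills the window
  up2 <- up; up2[9] <- 0.2
  expect_equal(nrow(assignPatterns(list(mkPair(up2, base, rep(0.8, n))), gb)),
               0L)

  # reverse direction uses the reverse p-values and negative mean difference
  ptr <- mkPair(base, up, rep(-0.8, n))
  dbr <- assignPatterns(list(ptr), gb)
  expect_equal(dbr$pattern, "01")

  # chromosome ends can never satisfy the window
  edge <- rep(0.01, n)
  dbe <- assignPatterns(list(mkPair(edge, base, rep(0.8, n))), gb)
  expect_equal(dbe$bin, 3:(n - 2))
})

test_that("the pattern universe has 3^C(n,2) - 1 members", {
  expect_length(enumeratePatterns(2), 2L)
  expect_length(enumeratePatterns(3), 26L)
  expect_length(enumeratePatterns(4), 728L)
  expect_false(any(enumeratePatterns(3) == "00,00,00"))
  expect_error(enumeratePatterns(1), "two conditions")
})

test_that("differential regions merge within 2 kb and resolve overlaps by p", {
  gb <- genomeBins(c(chr1 = 1e5))
  # same pattern, 1.5 kb apart -> one region peaked at the lower p
  db <- data.frame(bin = c(10L, 25L), pattern = "10", p = c(1e-3, 1e-5))
  r <- buildRegions(db, gb)
  expect_length(r, 1L)
  expect_equal(S4Vectors::mcols(r)$peak_bin, 25L)
  expect_equal(GenomicRanges::start(r) - 1L, 900)
  expect_equal(GenomicRanges::end(r), 2500)

  # 3 kb apart -> two regions
  db2 <- data.frame(bin = c(10L, 41L), pattern = "10", p = c(1e-3, 1e-5))
  expect_length(buildRegions(db2, gb), 2L)

  # overlapping regions of different patterns: lowest peak p labels the union
  db3 <- data.frame(bin = c(10L, 12L, 11L, 13L),
                    pattern = c("10", "10", "01", "01"),
                    p = c(1e-4, 2e-4, 1e-2, 5e-3))
  r3 <- buildRegions(db3, gb)
  expect_length(r3, 1L)
  expect_equal(S4Vectors::mcols(r3)$pattern, "10")
  expect_equal(S4Vectors::mcols(r3)$peak_p, 1e-4)
})

test_that("raising w0 only removes significant bins on fixed data", {
  set.seed(8)
  n <- 500
  A <- matrix(runif(n * 4, 0, 0.3), ncol = 4)
  for (x in sample(10:(n - 10), 10)) A[(x - 2):(x + 2), 1:2] <-
    runif(10, 0.7, 1)
  pm <- smallMatrix(A, c("c1", "c1", "c2", "c2"))
  sig <- function(w0) which(pValues(
    permutationPvalues(pm, c("c1", "c2"), w0 = w0, seed = 2L)) <= 0.05)
  expect_true(all(sig(0.5) %in% sig(0.1)))
})

test_that("enhancerDynamics tests every unordered condition pair", {
  set.seed(14)
  A <- matrix(runif(200 * 6, 0, 0.2), ncol = 6)
  colnames(A) <- sprintf("s%d", 1:6)
  pm <- probabilityMatrix(asplit(A, 2), rep(c("c1", "c2", "c3"), each = 2),
                          bins = genomeBins(c(chr1 = 200 * 100)))
  dyn <- enhancerDynamics(pm, seed = 1L)
  expect_equal(ncol(dyn$pairs), 3L)
  expect_named(dyn$pairTests, c("c1_vs_c2", "c1_vs_c3", "c2_vs_c3"))
})
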