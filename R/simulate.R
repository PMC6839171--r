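# Synthetic-data generator: plants enhancers and promoters with the
# nucleosome-flanking histone-mark anatomy on a negative-binomial background,
# and simulates expression counts coupled to planted enhancer activity
# within shared TADs. Everything is deterministic given the config seed.

#' Build a synthetic-data configuration
#'
#' Defaults describe the standard benchmark genome: 2 chromosomes of 1 Mb
#' (10,000 bins of 100 bp each), 2 conditions x 2 replicates, 160 planted
#' enhancers (30% active in every condition, the rest specific to one
#' condition in round-robin; about 104 active per condition, enough to
#' assemble the default 1000/150-region training sets), 60 active and 60
#' inactive promoters,
#' negative-binomial background at 2 reads/bin (dispersion 0.1), and planted
#' signal at 8x background. Enhancers carry Gaussian H3K4me1 + H3K27ac
#' nucleosome bumps (sd 100 bp) at +/- 200, 400 and 600 bp around an
#' accessible, signal-free center; active promoters carry the same geometry
#' with H3K4me3 + H3K27ac instead.
#'
#' @param seqlengths named chromosome lengths (bp)
#' @param binSize bin width (bp)
#' @param nConditions,nReplicates design
#' @param nEnhancers,nActiveProm,nInactiveProm planted element counts
#' @param sharedFrac fraction of enhancers active in all conditions
#' @param backgroundRate mean background reads per bin
#' @param strength signal enrichment multiplier over background
#' @param flankOffset bump offset from the element center (bp)
#' @param signalSd bump sd (bp)
#' @param dispersion negative-binomial dispersion of the background
#' @param minSpacing minimum distance between planted centers (bp)
#' @param tadWidth TAD tile width (bp)
#' @param seed RNG seed
#' @return a \linkS4class{SimConfig}
#' @export
simConfig <- function(seqlengths = c(chr1 = 1e6, chr2 = 1e6), binSize = 100L,
                      nConditions = 2L, nReplicates = 2L, nEnhancers = 160L,
                      nActiveProm = 60L, nInactiveProm = 60L,
                      sharedFrac = 0.3, backgroundRate = 2, strength = 8,
                      flankOffset = 200L, signalSd = 100, dispersion = 0.1,
                      minSpacing = 5000L, tadWidth = 200000L, seed = 1L) {
  sl <- as.integer(seqlengths)
  names(sl) <- names(seqlengths)
  new("SimConfig", seqlengths = sl, binSize = as.integer(binSize),
      nConditions = as.integer(nConditions),
      nReplicates = as.integer(nReplicates),
      nEnhancers = as.integer(nEnhancers),
      nActiveProm = as.integer(nActiveProm),
      nInactiveProm = as.integer(nInactiveProm),
      sharedFrac = sharedFrac, backgroundRate = backgroundRate,
      strength = strength, flankOffset = as.integer(flankOffset),
      signalSd = signalSd, dispersion = dispersion,
      minSpacing = as.integer(minSpacing), tadWidth = as.integer(tadWidth),
      seed = as.integer(seed))
}

simSampleNames <- function(cfg) {
  as.vector(outer(seq_len(cfg@nReplicates), seq_len(cfg@nConditions),
                  function(r, c) sprintf("cond%d_rep%d", c, r)))
}

simConditions <- function(cfg) {
  rep(sprintf("cond%d", seq_len(cfg@nConditions)), each = cfg@nReplicates)
}

# deterministic collision-free element placement: a jittered grid of
# candidate centers at minSpacing, snapped to bin centers
placeElements <- function(cfg) {
  margin <- cfg@flankOffset + 4L * cfg@minSpacing %/% 10L + 2000L
  nTotal <- cfg@nEnhancers + cfg@nActiveProm + cfg@nInactiveProm
  slots <- do.call(rbind, lapply(names(cfg@seqlengths), function(ch) {
    pos <- seq(margin, cfg@seqlengths[[ch]] - margin, by = cfg@minSpacing)
    data.frame(chrom = ch, pos = pos)
  }))
  if (nrow(slots) < nTotal)
    stop("genome too small for ", nTotal, " elements at minSpacing ",
         cfg@minSpacing, " (", nrow(slots), " slots)")
  pick <- sort(sample(nrow(slots), nTotal))
  jit <- round(runif(nTotal, -0.2, 0.2) * cfg@minSpacing)
  center0 <- as.integer(slots$pos[pick] + jit)
  center0 <- (center0 %/% cfg@binSize) * cfg@binSize + cfg@binSize %/% 2L
  kind <- sample(rep(c("enhancer", "active_promoter", "inactive_promoter"),
                     c(cfg@nEnhancers, cfg@nActiveProm, cfg@nInactiveProm)))
  conds <- sprintf("cond%d", seq_len(cfg@nConditions))
  activeIn <- character(nTotal)
  ei <- which(kind == "enhancer")
  nShared <- round(cfg@sharedFrac * length(ei))
  for (k in seq_along(ei)) {
    activeIn[ei[k]] <- if (k <= nShared) paste(conds, collapse = ",")
                       else conds[(k - nShared - 1L) %% length(conds) + 1L]
  }
  activeIn[kind == "active_promoter"] <- paste(conds, collapse = ",")
  activeIn[kind == "inactive_promoter"] <- ""
  data.frame(chrom = slots$chrom[pick], center0 = center0, kind = kind,
             active_in = activeIn, strength = rep(cfg@strength, nTotal),
             stringsAsFactors = FALSE)
}

# per-bin Poisson signal rate added by one element (vector over one chrom).
# Marked elements have an accessible (signal-free) center flanked by a phased
# nucleosome array: three nucleosomes per side at +/- 1, 2, 3 x flankOffset
# with decaying amplitude (1, 0.8, 0.5), so the enrichment domain spans about
# 1.5 kb, as histone-mark ChIP signal around regulatory elements does. Each
# element's nucleosome positions are jittered slightly (phasing is imperfect
# in real chromatin), which keeps planted elements from being byte-identical
# templates.
elementProfile <- function(kind, center0, binCenters, cfg) {
  amp <- cfg@strength * cfg@backgroundRate
  g <- function(mu, a) a * amp *
    exp(-(binCenters - mu)^2 / (2 * cfg@signalSd^2))
  nucArray <- function() {
    offs <- cfg@flankOffset * c(1, 2, 3)
    amps <- c(1, 0.8, 0.5)
    jit <- round(runif(6, -0.2, 0.2) * cfg@flankOffset)
    Reduce(`+`, mapply(function(o, a, j) g(center0 + o + j, a),
                       c(-offs, offs), rep(amps, 2), jit, SIMPLIFY = FALSE))
  }
  if (kind == "enhancer") {
    flanks <- nucArray()
    list(H3K27ac = flanks, H3K4me1 = flanks, H3K4me3 = 0)
  } else if (kind == "active_promoter") {
    flanks <- nucArray()
    list(H3K27ac = flanks, H3K4me1 = 0, H3K4me3 = flanks)
  } else {
    list(H3K27ac = 0, H3K4me1 = 0, H3K4me3 = 0)
  }
}

#' Simulate histone-mark coverage tracks with planted elements
#'
#' Draws negative-binomial background counts per bin for every sample and
#' mark, adds Poisson counts from each planted element in the samples of the
#' conditions it is active in, and draws a background-only input track shared
#' by all samples.
#'
#' @param cfg a \linkS4class{SimConfig}
#' @return list: \code{bins} (\linkS4class{GenomeBins}); \code{samples}
#'   (named list per sample, each a named list of raw-count
#'   \linkS4class{BinnedTrack}s for the three marks); \code{input}
#'   (\linkS4class{BinnedTrack}); \code{truth} (data.frame: chrom, center0,
#'   kind, active_in, strength); \code{conditions} (condition per sample)
#' @export
simulateTracks <- function(cfg) {
  gb <- genomeBins(cfg@seqlengths, cfg@binSize)
  n <- nBins(gb)
  sampleNames <- simSampleNames(cfg)
  conditions <- simConditions(cfg)

  withSeed(cfg@seed, {
    truth <- placeElements(cfg)

    # per-condition, per-mark signal rate over all bins
    binC0 <- binStart0(gb) + cfg@binSize %/% 2L
    chrom <- binChrom(gb)
    conds <- sprintf("cond%d", seq_len(cfg@nConditions))
    lambda <- lapply(conds, function(cd) {
      l <- lapply(HM_MARKS, function(m) numeric(n))
      names(l) <- HM_MARKS
      l
    })
    names(lambda) <- conds
    for (i in seq_len(nrow(truth))) {
      el <- truth[i, ]
      activeConds <- strsplit(el$active_in, ",", fixed = TRUE)[[1]]
      if (length(activeConds) == 0L) next
      onChrom <- which(chrom == el$chrom &
                       abs(binC0 - el$center0) <= 6 * cfg@signalSd +
                         4L * cfg@flankOffset)
      prof <- elementProfile(el$kind, el$center0, binC0[onChrom], cfg)
      for (cd in activeConds) {
        for (m in HM_MARKS) {
          lambda[[cd]][[m]][onChrom] <- lambda[[cd]][[m]][onChrom] + prof[[m]]
        }
      }
    }

    size <- 1 / cfg@dispersion
    samples <- lapply(seq_along(sampleNames), function(s) {
      cd <- conditions[s]
      trk <- lapply(HM_MARKS, function(m) {
        counts <- rnbinom(n, mu = cfg@backgroundRate, size = size) +
          rpois(n, lambda[[cd]][[m]])
        binnedTrack(gb, m, counts)
      })
      names(trk) <- HM_MARKS
      trk
    })
    names(samples) <- sampleNames
    input <- binnedTrack(gb, "input",
                         rnbinom(n, mu = cfg@backgroundRate, size = size))
    list(bins = gb, samples = samples, input = input, truth = truth,
         conditions = conditions)
  })
}

#' Tile the synthetic genome into TADs
#'
#' @param cfg a \linkS4class{SimConfig}
#' @return GRanges of non-overlapping TADs with \code{tad_id} metadata
#' @export
simulateTads <- function(cfg) {
  pieces <- lapply(names(cfg@seqlengths), function(ch) {
    starts0 <- seq(0L, cfg@seqlengths[[ch]] - 1L, by = cfg@tadWidth)
    GRanges(ch, IRanges(starts0 + 1L,
                        pmin(starts0 + cfg@tadWidth, cfg@seqlengths[[ch]])),
            seqlengths = cfg@seqlengths)
  })
  tads <- do.call(c, pieces)
  mcols(tads)$tad_id <- sprintf("tad_%d", seq_along(tads))
  tads
}

#' Labeled training pool from a simulated genome
#'
#' Turns the truth table of \code{\link{simulateTracks}} into the labeled
#' region pool consumed by \code{\link{assembleTrainingSet}}: planted
#' enhancers active in \code{condition} (centers jittered by up to
#' \code{jitter} bp, emulating the imprecision of recentering real training
#' enhancers on accessibility peaks), active and inactive promoters, and
#' random intragenic / intergenic background bins clear of any element.
#'
#' @param sim result of \code{\link{simulateTracks}}
#' @param genes GRanges of (synthetic) gene bodies for background sampling
#' @param condition condition whose active enhancers become positives
#' @param jitter maximum centering error (bp) applied to enhancer labels
#' @param nIntragenic,nIntergenic background bins to draw
#' @param seed RNG seed
#' @return labeled GRanges pool (metadata \code{label}, \code{center0})
#' @export
labelPoolFromTruth <- function(sim, genes, condition, jitter = 150L,
                               nIntragenic = 400L, nIntergenic = 1400L,
                               seed = 1L) {
  truth <- sim$truth
  activeEnh <- truth$kind == "enhancer" &
    vapply(strsplit(truth$active_in, ",", fixed = TRUE),
           function(x) condition %in% x, logical(1))
  withSeed(seed, {
    mkRegions <- function(df, label, width) {
      ctr <- df$center0
      if (label == "enhancer" && jitter > 0L)
        ctr <- ctr + as.integer(round(runif(nrow(df), -jitter, jitter)))
      gr <- GRanges(df$chrom, IRanges(ctr - width %/% 2L + 1L, width = width),
                    seqlengths = seqlengths(sim$bins))
      mcols(gr)$label <- label
      mcols(gr)$center0 <- ctr
      gr
    }
    pool <- c(mkRegions(truth[activeEnh, ], "enhancer", 1100L),
              mkRegions(truth[truth$kind == "active_promoter", ],
                        "active_promoter", 100L),
              mkRegions(truth[truth$kind == "inactive_promoter", ],
                        "inactive_promoter", 100L))
    bg <- sampleBackgroundBins(genes, pool, sim$bins, nIntragenic,
                               nIntergenic, seed = seed + 1L)
    mcols(bg)$label <- as.character(mcols(bg)$label)
    suppressWarnings(c(pool, bg))
  })
}

#' Simulate expression counts coupled to planted enhancer activity
#'
#' Assigns each planted enhancer a target gene whose TSS lies in the same TAD
#' (5-25 kb away, kept inside the TAD), plus condition-independent decoy
#' genes. A target gene's mean expression scales with its enhancer's activity
#' in each condition (baseMean in inactive, foldChange x baseMean in active
#' conditions); counts are negative-binomial per sample.
#'
#' @param truth truth table from \code{\link{simulateTracks}}
#' @param tads GRanges from \code{\link{simulateTads}}
#' @param cfg the \linkS4class{SimConfig}
#' @param nDecoys number of decoy genes (default 30)
#' @param baseMean baseline mean counts (default 100)
#' @param foldChange activity fold change (default 8)
#' @param exprDispersion NB dispersion of counts (default 0.05)
#' @return list: \code{counts} (genes x samples integer matrix), \code{tss}
#'   (GRanges with \code{gene_id}), \code{genes} (2-kb gene bodies, clipped
#'   at chromosome ends), \code{links} (data.frame: enhancer truth row,
#'   gene_id, active_in)
#' @export
simulateExpression <- function(truth, tads, cfg, nDecoys = 30L,
                               baseMean = 100, foldChange = 8,
                               exprDispersion = 0.05) {
  sampleNames <- simSampleNames(cfg)
  conditions <- simConditions(cfg)
  conds <- sprintf("cond%d", seq_len(cfg@nConditions))
  enh <- which(truth$kind == "enhancer")

  withSeed(cfg@seed + 7L, {
    # target genes: one per enhancer, TSS in the enhancer's TAD
    tadChrom <- as.character(seqnames(tads))
    genes <- lapply(seq_along(enh), function(k) {
      el <- truth[enh[k], ]
      ti <- which(tadChrom == el$chrom & start(tads) - 1L <= el$center0 &
                    end(tads) >= el$center0 + 1L)[1]
      offset <- sample(5000:25000, 1L) * sample(c(-1L, 1L), 1L)
      tss0 <- min(max(el$center0 + offset, start(tads)[ti] - 1L + 500L),
                  end(tads)[ti] - 500L)
      data.frame(gene_id = sprintf("target_%03d", k), chrom = el$chrom,
                 tss0 = as.integer(tss0), enhancer = enh[k],
                 active_in = el$active_in)
    })
    genes <- do.call(rbind, genes)
    decoyPos <- data.frame(
      gene_id = sprintf("decoy_%03d", seq_len(nDecoys)),
      chrom = sample(names(cfg@seqlengths), nDecoys, replace = TRUE),
      tss0 = NA_integer_, enhancer = NA_integer_, active_in = NA_character_)
    decoyPos$tss0 <- as.integer(
      runif(nDecoys, 2000, cfg@seqlengths[decoyPos$chrom] - 2000))
    all <- rbind(genes, decoyPos)

    mu <- matrix(baseMean, nrow = nrow(all), ncol = length(sampleNames),
                 dimnames = list(all$gene_id, sampleNames))
    for (k in seq_len(nrow(genes))) {
      activeConds <- strsplit(genes$active_in[k], ",", fixed = TRUE)[[1]]
      act <- conditions %in% activeConds
      mu[k, ] <- baseMean * ifelse(act, foldChange, 1)
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / exprDispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    tss <- GRanges(all$chrom, IRanges(all$tss0 + 1L, width = 1L),
                   seqlengths = cfg@seqlengths)
    mcols(tss)$gene_id <- all$gene_id
    bodies <- GRanges(all$chrom,
                      IRanges(all$tss0 + 1L,
                              pmin(all$tss0 + 2000L,
                                   cfg@seqlengths[all$chrom])),
                      seqlengths = cfg@seqlengths)
    mcols(bodies)$gene_id <- all$gene_id
    list(counts = counts, tss = tss, genes = bodies,
         links = genes[, c("enhancer", "gene_id", "active_in")])
  })
}
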