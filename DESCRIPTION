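Package: enhanceRF
Title: Enhancer Prediction, Condition Dynamics and Target Linking from
    Histone-Modification ChIP-seq
Version: 0.3.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts active enhancers genome-wide from three histone
    modifications (H3K4me1, H3K4me3, H3K27ac) with a two-tier random-forest
    classifier on 100-bp bins, assigns enhancers to experimental conditions
    with a non-parametric permutation test on per-bin enhancer probabilities,
    and links condition-specific enhancers to target genes by correlating
    enhancer probabilities with variance-stabilized expression within
    topologically associated domains. Includes a synthetic-data generator
    that plants enhancers, promoters and correlated target genes so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicAlignments,
    Rsamtools,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
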