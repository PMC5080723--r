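Package: hypomark
Title: Histone-Mark Dynamics Under Hypoxia and Reoxygenation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for broad histone-mark ChIP-seq time courses
    across hypoxia and reoxygenation. Normalizes H3K27me3 enrichment between
    samples via invariant high-intensity regions (20-kb windowed detection of
    above-percentile peak coverage, cumulative peak-area scale factors), sets
    an expression-validated background cutoff, calls per-gene H3K4me3 and
    H3K27me3 mark status within gene bodies plus 5-kb flanks, classifies
    H3K27me3-marked genes into Promoter, TSS and Broad enrichment profiles,
    tracks bivalent (H3K4me3 + H3K27me3) state transitions and retention
    across time points, and integrates log2 expression data (thresholding,
    group-median comparisons, two one-way ANOVA models with FDR control). A
    seeded synthetic-data generator produces peak landscapes, gene models and
    expression matrices with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
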