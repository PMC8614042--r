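Package: spliceprev
Title: Alternative Splicing Prevalence and Level from Splice-Junction Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates alternative splicing prevalence (ASP) and level (ASL)
    across species from splice-junction read counts. Junctions are merged,
    clustered into alternative-excision intron clusters and assigned to genes;
    gene-level ASL is the summed Shannon entropy of junction usage within
    clusters. Sequencing-depth under-detection is corrected by ranking genes
    by expression, binning them, and fitting a logistic saturation curve whose
    upper asymptote yields predicted ASP/ASL (PASP/PASL). A comparative layer
    relates ASP/ASL to organism complexity (cell type number) and intron-size
    statistics via Spearman and partial Spearman correlation, linear
    regression, and phylogenetic generalized least squares with maximum
    likelihood Pagel's lambda. A seeded simulator generates junction counts,
    annotations, coverage tracks, traits and trees with the statistical
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    ape,
    minpack.lm,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    optparse
Config/testthat/edition: 3
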