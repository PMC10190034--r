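Package: splicetree
Title: Consensus Splice-Impact Prediction with a Missing-Data-Tolerant Decision Tree
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates small variants (SNV, MNV, insertion, deletion, insdel)
    with bespoke splice features (exonic splicing enhancer/silencer position
    weight matrix deltas, AG/GT creation and removal, AG exclusion zone and
    branchpoint rules, U12 intron membership, minimal-intron violation, and
    donor/acceptor/exon/intron region classes), ingests score tables from
    external splice predictors, and combines everything through a C4.5-style
    decision tree that handles missing feature values by fractional instance
    weighting, returning a 0-1 splice-altering score per variant. Includes
    precision-recall threshold calibration, region-stratified evaluation, and
    a fully self-contained synthetic fixture generator (toy genome, gene
    models, planted variants, simulated external-tool scores, and delta-PSI
    based truth labels).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
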