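Package: cnvClonality
Title: Arm-Level CNV Clonality Trees from Single-Cell Copy-Number Calls
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of single-cell copy-number inference output into
    intra-tumor clonality trees. Converts per-subclone CNV region calls to
    chromosome-arm-level gain/loss events using cytoband arm boundaries,
    collapses subclones with identical arm-level events, reconstructs the
    nested evolutionary tree with inclusive cell percentages, corrects bulk
    driver-mutation allele frequencies for normal contamination by anchoring a
    truncal G-alpha mutation to 50%, attributes mutations to clones of like
    percentage, and renders deterministic SVG trees in which branch length is
    proportional to the percentage of cells plus a fixed spacer. Includes the
    upstream cell-QC and normal-reference-cell selection filters and a seeded
    synthetic-data generator with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xml2,
    ape,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CopyNumberVariation, SingleCell, Transcriptomics, Phylogenetics,
    Visualization
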