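Package: follireg3d
Title: Regulatory Landscape and 3D-Genome Statistics for Granulosa-Cell Folliculogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of stage-resolved multi-omics from avian
    granulosa cells: ROSE-style super-enhancer and super-silencer calling,
    Hi-C statistics (A/B compartment eigenvector, insulation-score TAD
    boundaries with a permutation-based stage-specificity test, intra-TAD
    contact strength, multi-resolution loop merging and loop-anchored
    enhancer-gene linking), stage-wise differential expression with
    specificity statistics (tau specificity index, Cliff's delta), and
    TAD-constrained TF-Enhancer-Target gene-regulatory-network inference
    with stability and permutation statistics. Ships a synthetic multi-omics
    generator with planted ground truth so every stage of the pipeline is
    testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
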