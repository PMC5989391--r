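Package: methylDirect
Title: Direct Methylation-Expression Regulatory Links by Conditional
    Mutual Information Network Pruning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers direct regulatory element (DRE)-target pairs linking
    CpG methylation to gene expression. A Gaussian mutual information /
    conditional mutual information estimator with permutation
    significance drives a PC-algorithm pruning of per-gene complete
    graphs over all genes and CpG probes within a genomic window of the
    target TSS. Downstream analyses include master regulator analysis
    with signed regulons and data-processing inequality filtering,
    transcription-factor binding enrichment by odds ratio,
    hypergeometric category enrichment, core regulatory circuitry
    assembly from super-enhancer-overlapping distal elements, and a
    three-node network motif census with randomized-network Z-scores.
    A seeded synthetic-data module generates regulatory scenes with
    known ground truth for calibration and false discovery rate
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    igraph,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: DNAMethylation, GeneExpression, NetworkInference, Epigenetics,
    GeneRegulation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
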