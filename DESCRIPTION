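Package: chirpnet
Title: Integrative Mapping of lncRNA Direct Target Genes from ChIRP-seq and
    Knockdown RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for enhancer-associated lncRNAs that are
    mapped to chromatin by ChIRP-seq with dual (EVEN/ODD) probe sets and
    perturbed by CRISPRi knockdown RNA-seq. Consensus binding elements are
    derived by probe-set intersection, assigned to nearest genes within a TSS
    window, and integrated with a negative-binomial differential test to
    classify direct versus indirect target genes. A hierarchical regulatory
    layer of lncRNA-dependent transcription factors is inferred by exact-p
    position weight matrix scanning of promoter windows, and the common
    direct-target core shared with a cooperating transcription factor's ChIP
    binding is derived by staged gene-list intersection. Includes a synthetic
    study generator with planted two-layer ground truth, hypergeometric
    over-representation with Jaccard term clustering, NanoString-style panel
    normalization, and the small quantification formulas used in qPCR-based
    validation assays.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    yaml,
    igraph,
    S4Vectors,
    IRanges,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
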