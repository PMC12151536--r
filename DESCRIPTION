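Package: regmap
Title: Regulatory Region Mapping from Histone-Mark Cistromes with
    Enhancer-Gene Association and CRISPRa Perturb-Seq Calling
Version: 0.1.0
Authors@R:
    person("Regmap", "Developers", email = "regmap@example.org",
           role = c("aut", "cre"))
Description: Tools for integrative analysis of regulatory regions from
    histone-mark ChIP-seq peak sets: putative enhancer calling from
    H3K27ac/H3K4me1 double-positive regions, geometric super-enhancer
    stitching (12.5 kb gap, 15 kb size rule), multi-sample consensus
    catalogs, enhancer-gene association by TSS window and chromatin-loop
    anchors, transcription-factor colocalization statistics,
    gene-signature activity scoring with expression correlation, and
    CRISPR-activation Perturb-seq gRNA assignment with activation and
    differential-expression calls. Includes seeded synthetic-data
    generators with planted ground truth for end-to-end validation, and
    a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    jsonlite,
    optparse,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
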