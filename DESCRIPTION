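Package: sweepscan
Title: Cross-Population Selective Sweep Scanning and Selected-Region Calling
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects genomic regions under selection between related
    subpopulations from biallelic SNP genotypes. Implements an XP-CLR
    composite-likelihood sweep scan in sliding windows, percentile-based
    selected-region calling with cross-comparison consensus, Weir-Cockerham
    F_ST and windowed nucleotide diversity for cross-validation, and
    region annotation (genes, QTL overlap, high-impact alleles,
    hypergeometric GO enrichment). Ships a seeded synthetic-data generator
    (drift + hitchhiking sweeps) so the full pipeline is testable without
    external genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
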