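Package: refstab
Title: Reference-Gene Stability Analysis for RT-qPCR
Version: 0.1.0
Authors@R: person("refstab", "developers", role = c("aut", "cre"),
    email = "refstab@example.org")
Description: Selection and validation of RT-qPCR reference (housekeeping)
    genes from raw quantification-cycle (Cq) tables. Implements the three
    standard stability algorithms (geNorm average expression stability M
    with the pairwise-variation V rule for how many reference genes to use,
    NormFinder model-based inter/intra-group variance decomposition, and
    the BestKeeper index with correlation-based ranking), geometric-mean
    consensus ranking across methods, primer-efficiency estimation from
    dilution series, delta-delta-Cq relative quantification of target genes
    under configurable reference-gene sets, and a synthetic Cq generator
    with known ground truth so every pipeline stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
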