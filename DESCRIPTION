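Package: sh3map
Title: SH3 Domain Interactome Analysis from Phage-Display Specificities and Yeast Two-Hybrid Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds position weight matrices (PWMs) of SH3 domain binding
    specificity from aligned phage-display peptides, scans and ranks proteomes
    for candidate ligand motifs, and assembles a high-confidence SH3 domain
    interactome from raw yeast two-hybrid candidates by integrating colony
    counts, literature evidence and motif matches. Downstream analyses include
    a PWM similarity tree, cross-species interaction-conservation tests with a
    corrected interaction universe, binding-site-resolution rewiring
    classification, motif-competition statistics, information-content-based
    annotation semantic similarity benchmarking, and modified k-core
    guilt-by-association function prediction with cross-validated ROC
    evaluation. A seeded synthetic-data generator produces every input the
    pipeline consumes, with ground-truth labels for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
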