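Package: phosphowalk
Title: Random-Walk Chain Inference for Phospho-Antibody Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pan- and phosphosite-specific antibody
    microarray screens (KAM-1325/KAM-2000 style designs) comparing a treated
    sample against a control. Implements the array quality filters (low-signal,
    relative-error and total-error rules), percent-change-from-control and
    log2 fold-change computation, mapping of measurements onto a signed
    directed kinase-substrate network, seeded random-walk inference of
    phosphorylation chains with inhibition-aware termination, single-path
    imputation, a permutation null for chain enrichment, parallel-
    phosphorylation resolution and depth/effect-size chain selection, and
    assembly of up- and down-regulated chains into a styled comparative
    pathway map (GraphML/DOT/JSON export). Ships a synthetic-array generator
    with planted signalling cascades so the full pipeline can be benchmarked
    by planted-cascade recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
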