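Package: CoExSig
Title: Cross-Tissue Co-Expression Module Signatures via Literature
    Concept Profiles
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects trait-associated gene co-expression modules in two
    tissues with a weighted correlation network analysis (soft-threshold
    adjacency, topological overlap, dynamic branch cutting, eigengene
    merging, Pearson module-trait correlation), annotates every module
    with literature-derived concept profiles in four semantic categories
    (co-occurrence relations weighted by the symmetric uncertainty
    coefficient, matched by inner product), scores all cross-tissue
    module pairs by annotation overlap, and assesses pair significance
    with a random-module permutation null combined with Westfall-Young
    minP familywise error control. A synthetic-data generator with
    planted modules, trait effects and a planted document corpus makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
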