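Package: tfscope
Title: Time-Course Two-Color Microarray Analysis with Total Flag Sum
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-course two-color (competitive
    hybridization) microarray experiments: dye-swap ratio combination with
    inverse-variance weighting, combined fold-change and p-value filtering
    with an apparent false discovery rate estimate, Total Flag Sum (TFS)
    encoding of per-array significance patterns and classification of genes
    into early/mid/late temporal response subgroups, principal component
    analysis of the standardized ratio matrix by singular value
    decomposition, de novo promoter motif discovery with a ZOOPS Gibbs site
    sampler followed by Fisher exact enrichment against expression-defined
    background gene sets, gene-set over-representation tests, and
    comparative-Ct qPCR fold-change validation. Includes a synthetic-data
    generator that plants temporal response archetypes, probe redundancy,
    dye bias and promoter motifs with known ground truth, so every stage of
    the pipeline can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    limma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
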