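Package: reoxflow
Title: Transcriptional Dynamics of Tumor Cells During Reoxygenation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bulk expression time courses of tumor
    cells returning to normoxia after a hypoxic episode. Provides quantile
    normalization of background-adjusted array intensities, per-timepoint
    Student's t-tests against the hypoxia baseline with strict p-value
    selection of oxygen-responsive genes, response-dynamics bookkeeping
    (first-appearance times, direction calls, relative expression profiles),
    sample-level principal component analysis, hypergeometric gene-set
    over-representation against user-supplied pathway collections, a
    conservation-weighted position-weight-matrix promoter scanner with
    core/matrix similarity scores, and a tolerant microRNA seed-site search
    in 3'UTRs allowing one mismatch, G:U wobble, deletion, or insertion.
    A synthetic-data generator with ground-truth records makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
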