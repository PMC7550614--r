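Package: pesignet
Title: Early-Pregnancy Transcriptome Signatures and Interactome Modules of Preeclampsia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-product differential expression with permutation-based
    percentage-of-false-prediction estimates across four overlapping maternal
    conditions (preeclampsia, asthma, excess BMI, vitamin D insufficiency),
    replication filtering and exclusive-intersection signature analysis,
    confidence-filtered protein-protein interaction module construction with
    randomization-based edge-enrichment and module-closeness Z-scores,
    GO-style over-representation analysis and Wang-method semantic similarity
    with best-match-average aggregation, and cross-tissue (placental)
    replication of a blood-derived signature. Includes a seeded synthetic-data
    generator emulating the statistical structure of the study design so the
    full workflow runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    data.table,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
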