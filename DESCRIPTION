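Package: scgrnet
Title: Single-Cell Co-Expression Modules, Regulatory Networks and Drug Overlays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Workflow for single-cell expression data that aggregates cells
    into representative pseudo-cells, infers weighted gene co-expression
    networks and modules (soft-thresholded adjacency, topological overlap,
    eigengenes, hubs, trait correlations, scale-free fit), converts a module
    of interest into a directed transcription-factor regulatory network via
    gradient-boosted regression with cis-regulatory motif enrichment
    filtering, and overlays drug-target associations from a local snapshot
    table into one combined typed graph. Includes a negative-binomial
    synthetic-data generator with planted modules, driver transcription
    factors, motif rankings and a toy drug table so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    rpart,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
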