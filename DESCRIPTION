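Package: fusenet
Title: Domain-Based Network Inference of Gene-Fusion Pathways and Targets
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the molecular interaction partners of a gene fusion from
    the protein domains it retains from its two parental genes, scores all
    genes of a compiled gene network for functional association with the
    fusion by random walk with restart, identifies associated pathways by
    rank-based (GSEA-style) enrichment with permutation p-values, integrates
    expression-based deregulation evidence via the truncated product method
    for combining p-values, and prioritizes drugs and synergistic targets
    among the top-ranked genes. Includes a deterministic synthetic-data
    generator with planted network modules for end-to-end benchmarking, and
    a command-line interface covering the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
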