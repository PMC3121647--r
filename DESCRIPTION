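Package: synton
Title: Exact Quorum-Aware Synteny Block Detection Across Multiple Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects conserved synteny blocks ("syntons") across n gene-ordered
    genomes from a pairwise, many-to-many gene correspondence relation. Genomes
    are modelled as interval graphs on gene ranks (linear or circular, with a
    gap radius), the correspondence relation is aggregated into multi-genome
    spines (cliques, connected components or gamma-quasi-cliques), and syntons
    are the maximal spine sets that are connected on every covered genome. A
    quorum parameter allows blocks missing from up to n - q genomes via
    don't-care slots. Provides both an explicit, definition-driven brute-force
    partitioner used as an oracle and a depth-first on-the-fly engine that
    never materialises the full alignment multigraph, plus BLAST tabular pair
    filtering, a seeded synthetic-data generator with planted blocks,
    projection and maximality post-processing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
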