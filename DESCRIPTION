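Package: pangraph
Title: Pangenome Gene Graphs and Generalized Bibubble Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bidirected gene graphs from protein-to-genome alignments
    (miniprot-style PAF) of multiple genome assemblies, encoding each contig as
    a walk of oriented genes. Resolves redundant and orthologous protein hits
    into a consistent per-genome gene annotation, scores and filters graph
    edges, and detects gene order, copy-number and orientation variation as
    generalized bibubbles defined on the bidirected graph via net graphs and
    cycle equivalence. Includes GFA 1.1 input/output with walks, core/accessory
    gene classification, a seeded pangenome simulator with ground truth, and
    brute-force oracles for the bubble and cycle-equivalence machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
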