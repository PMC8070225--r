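Package: SMCsurvey
Title: Typing, Protein Families, Similarity Networks and Alien Index
    Screening for Fungal Secondary Metabolite Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for batch surveys of candidate secondary metabolite
    biosynthetic gene clusters (SMCs) in fungal genome assemblies. Reads
    cluster regions exported as GenBank records together with tabular
    protein-domain and protein-homology hits, curates and types clusters
    with a configurable Pfam/InterPro rule engine, infers protein families
    with a from-scratch Markov Cluster Algorithm (with silhouette-width
    parameter sampling), builds a synteny-aware cluster-similarity network
    weighted by average sequence identity, and screens cluster genes for
    putative bacterial origin with the Alien Index statistic. A seeded
    synthetic-data generator with planted truth exercises every stage
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    Biostrings,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
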