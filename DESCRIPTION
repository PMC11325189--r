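Package: funfamer
Title: Clustering Protein Domain Superfamilies into Functional Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions protein domain superfamilies into functional
    families (FunFams) from sequence identity clusters, source-agnostic
    distance half-matrices over cluster representatives (embedding or
    structural distances), agglomerative relationship trees, and
    differential-conservation tree cutting. Implements three
    orchestration protocols (single-pass, multi-domain-architecture
    prepartitioning, and random-splitting with a merging second
    iteration), EC-purity and alignment-diversity benchmarking, and a
    seeded synthetic-superfamily generator with planted families and
    specificity-determining positions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    mclust,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
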