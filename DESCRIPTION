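Package: ribomorph
Title: Assembly and Phasing of Ribosomal DNA Morphs from Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles full-length ribosomal DNA (rDNA) repeat units ("morphs")
    from a combination of highly accurate long reads (PacBio HiFi-like) and
    ultralong noisy reads (Oxford Nanopore-like). A reference repeat sequence
    recruits accurate reads by shared k-mers; a homopolymer-compressed de
    Bruijn unitig graph (the allele graph) captures all within-repeat
    variation; ultralong reads are aligned to the graph and complete
    repeat-unit traversals ("loops") are extracted from the alignment paths,
    clustered by pairwise edit distance (union-find rough clusters, then
    DBSCAN density clusters with a data-driven epsilon), and polished into
    per-cluster consensus morphs. Includes a simulator of mosaic rDNA arrays
    with known ground truth, read simulation with platform-like error
    profiles, and evaluation utilities implementing a rotation-aware
    99 percent identity / 99 percent coverage morph matching criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    Biostrings,
    withr,
    optparse
Config/testthat/edition: 3
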