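Package: circassess
Title: Rotation-Invariant Assessment of Circular Replicon Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating long-read assemblies of circular
    prokaryote replicons (chromosomes and plasmids). Contiguity is
    measured as the longest single alignment of an assembly against a
    tripled copy of the circular reference, which makes the metric
    invariant to the arbitrary start position of a circular contig and
    tolerant of start-end overlap. Additional metrics include
    CIGAR-derived consensus identity and maximum indel size, plus a
    four-way assembly completeness classifier. The package also provides
    reference-genome quality-control filters and panel selection, a
    read-simulation parameter sampler, depth-targeted read subsampling,
    and a synthetic fixture generator producing defective assemblies
    with exact ground-truth alignments, so the whole assessment pipeline
    is testable without external data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
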