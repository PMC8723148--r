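Package: tidysv
Title: Tidy Linked-Table Toolkit for Structural Variant Calls and SV
    Signature Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Normalizes structural variant (SV) calls from the VCF dialects
    of four popular short-read SV callers (Manta, Delly, Lumpy, Gridss) and
    from BEDPE files into a tidy linked-table data model, then supports
    interval-tree annotation against BED files, declarative filtering on
    coordinates, INFO and FORMAT fields, multi-caller merging under
    proximity or confidence-interval criteria, breakpoint microhomology
    inference from a reference genome, user-defined SV classification into
    per-sample feature matrices, and SV signature extraction by
    non-negative matrix factorization with cluster-stability rank
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    cluster,
    dplyr,
    pracma,
    readr,
    stats,
    tibble,
    tools,
    utils,
    vcfR
Suggests:
    igraph,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
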