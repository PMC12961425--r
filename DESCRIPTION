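Package: mycomob
Title: Curation and Comparison Toolkit for Fungal Transposable Element
    Consensus Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to curate transposable element (TE) consensus libraries
    the way large multi-genome fungal TE databases are built: six-frame
    translation with residue-to-nucleotide coordinate projection, parsing
    and filtering of protein-search hit tables (tabular BLAST/DIAMOND and
    HMMER domain tables), interval-algebra based removal of putative host
    genes, protein-evidence concordance labelling (PE/DA/NE), sequence and
    genome quality flagging (length, N content, N50, BUSCO), 80-80-80
    family clustering with a reference greedy implementation, a persistent
    family/member naming grammar, and base-pair resolution comparison of
    competing TE annotation sets. A deterministic synthetic-fixture
    generator with independently computed ground truth makes every step
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    Rcpp,
    tibble,
    dplyr,
    readr,
    yaml,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
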