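Package: covres
Title: Multi-Mapper Read Resolution by Coverage Variance Minimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processes SAM/BAM alignment files so that every read (or
    read pair) retains exactly one alignment. Ambiguously mapped reads are
    assigned to the candidate location that makes the read coverage as
    uniform as possible, by iteratively minimising the empirical variance of
    coverage in local windows around the competing alignments. Includes
    paired-end proper-pair enumeration, edit-distance candidate filtering,
    annotation-aware window trimming for spliced RNA-seq alignments, and a
    synthetic-fixture generator (repeat-structured genomes, exhaustive
    tiling alignments) for download-free validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
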