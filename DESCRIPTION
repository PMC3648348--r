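Package: matescaffold
Title: Mate-Pair Library Evaluation, Repeat Bridging and Contig Scaffolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates paired-end and mate-pair sequencing libraries
    (insert sizes from 170 bp to 25 kb) over synthetic genomes with
    mammalian-like repeat landscapes, and evaluates their value for genome
    structure analysis: read-pair classification (clonal, remote, inverted,
    everted), insert-size estimation, library complexity and saturation,
    physical coverage and coverage normalization, repeat-element bridging
    statistics, SSPACE-style greedy contig scaffolding with N50 evaluation
    of library combinations, and concordance of scaffold arrangements with
    in-silico or optical-map-like restriction maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    graphics,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
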