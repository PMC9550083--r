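Package: indelmarker
Title: Design and Application of Subspecies-Discriminating InDel Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk pipeline for developing PCR-based insertion/deletion
    (InDel) markers that discriminate two subspecies groups from
    per-accession variant calls: InDel normalization and group-common
    cataloguing, subspecies-specific InDel selection, flanking-template
    extraction, constraint-driven primer design with nearest-neighbor
    melting temperatures and genome-uniqueness screening, in-silico PCR
    with virtual-gel marker classification and physical-map export, and
    downstream marker application (binary band matrices, discrimination
    reports, genetic distance, UPGMA clustering). Includes a fully
    seeded synthetic-cohort generator with planted variant classes so
    the whole pipeline can be exercised and validated without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
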