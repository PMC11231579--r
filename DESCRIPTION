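Package: vcftally
Title: Summarize, Compare and Inspect Variant Call Format Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native toolkit for working with Variant Call Format
    (VCF) files: reading and writing plain or gzip-compressed VCF,
    normalization (splitting multiallelic sites and removing duplicate
    variant keys), classification of variants into transitions,
    transversions, insertions, deletions, multinucleotide polymorphisms and
    assorted variants, summary statistics (per-contig class counts, Ts/Tv
    ratio, INDEL size distribution, windowed variant density), pairwise
    comparison of variant sets with Venn counts, and a composable
    filter/search/sort engine over the eight fixed VCF columns. A seeded
    synthetic-VCF generator with exact machine-readable ground truth makes
    every operation testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
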