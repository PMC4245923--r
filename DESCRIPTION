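Package: hlarray
Title: HLA Class I Typing from Tiling Oligonucleotide Probe Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sequence-specific oligonucleotide probe (SSOP) array
    based HLA class I typing. Designs complete overlapping (single-nucleotide
    tiling) probe sets with melting-temperature driven length adjustment,
    normalizes raw array fluorescence to a fixed 1-20,000 scale, corrects
    outlier probe signals using the overlapping-probe structure, and calls
    genotypes at 4-digit resolution in three stages: serotype ranking by
    negative-probe counts, allele selection via comparison vectors and a
    knowledgebase of previously typed template arrays, and genotype-level
    ambiguity removal. A hybridization simulator generates allele catalogs
    with controlled serotype structure and synthetic probe signals so every
    stage can be exercised without real array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
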