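Package: protascan
Title: Entropy-Based Conservation Analysis of Protamine Sequence Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds homologous groups of sperm protamine sequences from
    UniProt-style records, scores every multiple-sequence-alignment column
    with a gap-weighted Kullback-Leibler relative-entropy conservation score
    against background amino-acid frequencies, calls conserved positions
    using an all-arginine score threshold, and compares arginine-lysine
    density distributions between groups (whole-sequence and DNA-binding
    region) with Welch's t-tests. Includes a synthetic protamine-family
    generator with planted conserved columns so the full pipeline is
    testable without database downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
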