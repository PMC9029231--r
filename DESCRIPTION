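Package: flexsite
Title: Flexible-Threshold, Conservation-Aware Transcription Factor
    Binding Site Over-Representation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects over-represented transcription factor binding sites in
    promoter sets using information-content-weighted position weight matrix
    scanning, an exhaustively optimized ("flexible") score threshold subject
    to a control-set site-frequency constraint, rank-based cross-species
    conserved scores, location-based grouping of redundant matrices, a
    resampling group-wise false discovery rate, and flanking-region analysis
    of composite elements. Includes a regulatory-class gene classifier for
    two-genotype injury time-course contrasts and fully seeded synthetic-data
    generators (promoter corpora, ortholog bundles, expression contrasts)
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
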