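Package: panelcov
Title: Capture and Coverage Adequacy Assessment for Clinical Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses whether exome capture and sequencing depth are adequate
    to detect catalogued variants across a clinical gene panel. Provides
    interval algebra for panel exons and capture designs, per-exon covered
    fraction classification at a depth threshold into five tiers (fully,
    well, mostly, lightly, not covered), partitioning of a variant catalogue
    by class and position multiplicity, per-position detectability binning by
    sequencing depth, diagnostic triage of case findings into positive,
    uncertain, and negative verdicts, and a seeded synthetic-data generator
    with machine-readable ground truth so every stage of the pipeline can be
    verified at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
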