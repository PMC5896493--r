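Package: haplotidy
Title: Haplotype Extraction from COI Metabarcoding Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts intraspecific haplotypes from COI amplicon (metabarcoding)
    data by combining strict read quality filtering, pooled abundance-skew
    denoising, greedy centroid OTU clustering and multi-level abundance
    thresholds. Produces haplotype-by-sample tables, minimum-spanning haplotype
    networks, per-site frequency exports and replicate-consistency statistics,
    and ships a mock-community read simulator with full ground truth for
    validating the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    stringi,
    ggplot2,
    readr,
    withr,
    generics,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
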