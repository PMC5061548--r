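Package: retroexpand
Title: Simulation and Inference of Retrogene Family Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the expansion of processed-pseudogene (retrogene)
    families such as the elephant TP53 repertoire. Provides a seeded
    generator of dated species trees, birth-death gene-family histories,
    retrogene sequences with a diagnostic deletion, segmentally duplicated
    loci with transposable-element fingerprint flanks, shotgun read sets
    (modern and ancient profiles) and expression tables; a repertoire
    toolkit (Smith-Waterman local alignment, reciprocal best hits, ORF and
    coding-potential assessment, diagnostic-indel discovery, amplicon
    prediction, duplication-mechanism classification); three complementary
    copy-number estimators (1:1-ortholog minimum, normalized read-depth
    average with bootstrap confidence interval, and dated gene-tree
    reconciliation maximum with unsampled-gene rules); and
    copies-through-time trajectories correlated against body-size series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
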