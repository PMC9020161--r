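Package: ddnscreen
Title: Network-Based Drug Repurposing by Transcriptomic Signature Reversal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a unified signed human pathway graph from pathway edge
    lists, selects per-subtype disease driver genes from copy-number and
    expression cohorts (G-score aberration statistic, Fisher's exact test,
    common-variant exclusion, chi-square expression ranking), assembles
    shortest-path drug-disease subnetworks, and scores drugs and additive
    drug pairs by Pearson anti-correlation between drug perturbation
    z-scores and disease signature z-scores. Includes a seeded synthetic
    data generator with planted ground truth for every pipeline stage, a
    drug-drug interaction post-filter, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
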