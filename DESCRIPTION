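Package: seedshift
Title: Seed-Match Specificity and Pharmacology Analysis for Chemically
    Modified siRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating the off-target specificity and
    pharmacology of chemically modified, GalNAc-conjugated siRNAs.
    Parses an ASCII notation for 2'-OMe/2'-F/GNA-modified duplexes with
    phosphorothioate linkages, derives guide-strand seeds and canonical
    target-site sequences (mer8, mer7m8, mer7A1), scans 3'-UTR sets for
    seed matches, and quantifies seed-mediated repression as stratified
    cumulative-distribution shifts of log2 fold-changes with
    Kolmogorov-Smirnov and rank-sum tests and dose-response profiles.
    Also provides first-derivative melting-temperature estimation from UV
    melting curves with Delta-Tm bookkeeping, delta-delta-Ct and
    dual-luciferase quantification, theoretical metabolite truncation
    ladders with mass accounting, and a deterministic synthetic-data
    generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
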