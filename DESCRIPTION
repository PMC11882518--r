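Package: mirarch
Title: MicroRNA Hairpin Filtering, Seed Target Prediction and Target-Set
    Enrichment for Branchial Arch Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small RNA-seq based discovery of candidate
    microRNA regulators in embryonic branchial arch tissue. Provides a
    read-stack based high-confidence filter for novel pre-microRNA
    hairpins (arm support, 5' homogeneity, 3' overhang, sub-hairpin and
    folding-energy criteria), seed-match target prediction over 3'UTRs
    with the five-class site taxonomy (8mer, 7mer-m8, 7mer-A1, 6mer,
    off-6mer) and a nearest-neighbour duplex hybridisation energy,
    expression (CPM) and differential-expression filtering, and
    per-microRNA hypergeometric enrichment against a domain-specific
    gene set. Seed-controlled synthetic-data generators emulate each
    input with planted ground truth, so every stage can be validated
    end to end.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
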