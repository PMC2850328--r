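Package: replikit
Title: Stoichiometric Autocatalysis Detection and Replicator Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the formal analysis of replicators. Detects and
    classifies autocatalysis in small stoichiometric reaction networks
    (orders, exact replication ratios, minimal autocatalytic seeds,
    autonomous versus dependent versus autoinductive roles) via a bounded
    token-game reachability search; models selection as phenotype-induced
    equivalence partitioning of entity sets, with the standard genetic
    code as a worked fixture; classifies hereditary potential in the S/N
    (states versus population size) and V/H (variable versus heritable
    fraction) frameworks, including a closed-form expected parent-offspring
    similarity; and provides a stochastic population simulator of modular
    replicators that serves as a Monte-Carlo cross-check of the closed
    forms and demonstrates selection among exact replicators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
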