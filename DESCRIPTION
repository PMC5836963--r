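Package: molfrag
Title: Exhaustive Molecular Fragmentation with Cut-Point Capping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fragments molecules at bonds matched by SMARTS cleavage rules
    (built-in RECAP, BRICS, CCQ and an extendedRECAP-style extension, or
    user-defined rule files), then combinatorially recombines the smallest
    fragments into every connected intermediate fragment of up to k pieces.
    Cut points are capped with hydrogens or with dummy atoms that preserve
    the original bonding pattern. Fragment sets can be filtered by heavy-atom
    count, size relative to the parent, molecular weight and the
    rule-of-three panel, and aggregated into fragment libraries with
    frequency statistics, summaries and plots. Molecular perception is
    delegated to RDKit via a bundled Python worker.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH (override with the MOLFRAG_PYTHON environment variable).
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    rlang,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
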