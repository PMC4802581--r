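Package: congrue
Title: Gene-Tree Congruence Diagnostics for Rapid Radiations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing rapid radiations from phylogenomic data:
    per-locus alignment informativeness profiles (taxa, length, variable
    sites, parsimony-informative characters, missing data), gene-tree versus
    species-tree bipartition congruence tallies with missing-taxon-aware
    constraint pruning, and the association between congruence and branch
    duration on a chronogram.  Includes a multispecies-coalescent synthetic
    data generator with taxon dropout emulating sequence-capture
    inefficiency, so every pipeline stage can be exercised and verified
    without external data.  Results are tibbles designed for piped
    workflows, with broom-style tidy()/glance() methods and ggplot2
    autoplot() support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
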