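Package: icscreen
Title: Intercellular CRISPR Screens for Ligand-Receptor Target Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combines gene-level scores from paired genome-wide CRISPR
    screens -- one in immune cells, one in cancer cells, obtained while the
    two cell types interact -- over a ligand-receptor interaction catalog to
    produce an intercellular normZ score per interaction. Implements the
    drugZ-style empirical-Bayes guide-to-gene normZ statistic, expression
    gating of unexpressed genes, Stouffer combination across the
    ligand-receptor pair and across cancer cell lines under Tolerant, Strict
    and Composite sign rules, per-direction false discovery rates, gene-level
    aggregation, candidate shortlisting, and three-class evaluation against
    curated standards (macro-averaged precision, recall, F1 and AUROC). A
    negative-binomial simulator generates complete synthetic screen inputs
    with planted effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
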