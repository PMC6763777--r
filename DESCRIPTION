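Package: drugsimnet
Title: Drug Repurposing via Pathway-Level Drug Functional Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a drug-drug functional similarity network from the
    correlation between pathway activity profiles (single-sample gene set
    enrichment of mRNA and microRNA expression) and drug activity profiles
    across a cancer cell-line panel, then prioritizes candidate drugs for a
    cancer of interest by random walk with restart from a seed set of
    approved drugs. Includes a degree-preserving permutation test for the
    empirical significance of prioritization scores, leave-one-out
    cross-validation with ROC/AUROC evaluation, a synthetic cell-line-panel
    generator with planted drug modules for end-to-end validation, and a
    one-shot pipeline runner with a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
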