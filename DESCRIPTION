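Package: brainmetsig
Title: Consensus Brain-Metastasis Expression Signature Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of transcriptomic signatures shared by brain
    metastases of different primary cancers. Implements a two-step
    selection workflow on gene-by-sample log2 expression matrices: a
    Kruskal-Wallis cross-type filter on brain-metastasis samples followed
    by per-cancer-type significance analysis of microarrays (SAM) with a
    modified t-statistic, a data-driven fudge factor and permutation-based
    empirical q-values; consensus intersection across cancer types;
    gene-wise generalized-linear-model confirmation with false-discovery-rate
    control; and per-gene inverse-variance fixed-effects meta-analysis of
    log2 fold changes across external datasets. Ships a seeded synthetic
    cohort generator emulating a three-cancer brain/extra-cerebral design
    with planted signature genes, plus the downstream quantification
    statistics used for validation (2^-ddCt relative quantification,
    immunohistochemistry scoring, Cohen's kappa, Mann-Whitney and Pearson
    tests, metastatic surface-area ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1.0)
Imports:
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    e1071,
    cluster
Config/testthat/edition: 3
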