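Package: oncofunnel
Title: Integrative Prioritization of Prognosis-Related Cancer Genes from
    Copy-Number and Expression Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing prognosis-related cancer
    genes by integrating literature keyword curation, per-gene somatic
    copy-number gain/loss classification, Z-score over-expression calling in
    matched tumour samples, and gain/over-expression concordance counting,
    followed by hypergeometric gene-set enrichment, OncoPrint-style cohort
    alteration summaries, Kaplan-Meier/log-rank survival comparison of
    altered versus unaltered samples, and seed-neighborhood summaries of an
    interaction network. Includes a deterministic synthetic cohort generator
    with planted driver genes so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
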