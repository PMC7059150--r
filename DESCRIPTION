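Package: agewise
Title: Healthy Versus Common Aging Transcriptome Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies bulk RNA-seq cohorts into tissue-level healthy,
    common and disease cohorts from donor disease annotations, detects
    age-associated genes per cohort with a covariate-adjusted per-gene
    linear model under Benjamini-Hochberg FDR control, performs
    precision-weighted moderated-t differential expression between disease
    and healthy tissue, partitions aging genes into core, common-specific
    and healthy-specific sets, measures direction concordance between
    aging and disease regulation, and tests hypergeometric overlap with
    external gene sets and disease-gene catalogs. Ships a synthetic-data
    generator that reproduces the age-to-disease-to-expression confounding
    structure with known ground truth, so the whole pipeline runs and is
    validated without any protected data.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
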