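Package: stromabalance
Title: Stroma-Balanced Differential Expression for Heterogeneous Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Minimizes stroma-tissue confounding in cancer-versus-normal
    differential expression analysis of bulk prostate tissue cohorts.
    Derives stroma-enriched and stroma-depleted gene-sets from cohorts with
    histopathology by comparing p-values between stroma-balanced and
    stroma-unbalanced contrasts, scores stroma content per sample with a
    rank-based single-sample enrichment statistic, stratifies cohorts into
    balanced and unbalanced datasets, and combines cohorts in a
    rank-normalized Mann-Whitney meta-analysis. Includes a synthetic
    tissue-mixture cohort generator with planted gene classes for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
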