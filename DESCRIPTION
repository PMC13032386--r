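Package: fiberomics
Title: Myofiber-Level Proteomics: Missingness Filtering, Left-Censored
    Imputation and Fiber-Subtype Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for laser-capture-microdissection
    mass-spectrometry (LCM-MS) protein-group matrices from single
    myofiber subtypes. Implements replicate-support and donor-support
    missingness filters, QRILC left-censored imputation (quantile
    regression on the observed upper tail with truncated-normal draws),
    log2 median normalization, replicate averaging, differential
    expression with Benjamini-Yekutieli FDR control, presence-absence
    fiber-subtype signature classification, and gene-set / cross-study
    overlap annotation. Includes a synthetic-data generator with
    intensity-dependent (left-censored, missing-not-at-random)
    detection so every stage is testable without raw instrument data.
License: MIT
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
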