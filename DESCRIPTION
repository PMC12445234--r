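Package: cbcsig
Title: Cutoff Behavioral Criteria Scoring and Stress-Signature Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for classifying stress-exposed animals as resilient or
    vulnerable with composite Cutoff Behavioral Criteria (CBC) scores, and for
    deriving region-specific transcriptomic resilience and susceptibility gene
    signatures from pairwise differential-expression overlaps. Includes a
    seeded synthetic-cohort generator (behavioral battery measurements,
    acoustic startle traces, physiology, and negative-binomial RNA-seq counts
    with planted fold changes), startle-response metrics, percentile-based
    threshold scoring and phenotype classification, TPM quantification, a
    calibrated negative-binomial Wald test with dispersion shrinkage,
    gene-set overlap signature extraction with an outlier-robustness filter,
    and a reproducible end-to-end pipeline.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
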