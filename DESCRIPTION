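Package: vitdmr
Title: Mendelian Randomization of Vitamin D Status on Cardiovascular Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-data two-sample Mendelian randomization analysis of
    serum 25-hydroxyvitamin D on time-to-event and binary cardiovascular
    endpoints in a high-risk hypertensive-diabetic population. Builds an
    unweighted three-SNP allele-count genetic risk score instrument with
    Hardy-Weinberg and pairwise linkage-disequilibrium quality control and
    first-stage strength diagnostics (partial R-squared, F statistic); fits
    Cox proportional hazards (Efron ties), Kaplan-Meier/log-rank, and
    logistic endpoint models; and forms Wald-ratio causal estimates per
    ng/mL of 25(OH)D with confidence intervals from Fieller's theorem,
    including per-SNP and deficiency-subgroup sensitivity analyses. A
    synthetic-cohort generator reproduces the statistical structure of the
    study design (derivation and outcome subcohorts, Hardy-Weinberg
    genotypes, calibrated first-stage strength, proportional-hazards events
    with censoring) so the whole pipeline is testable without access to the
    original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
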