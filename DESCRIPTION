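Package: ovascreen
Title: Variant Prioritization and Biomarker Screening for Ovarian Tumor Panels
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a targeted-panel variant
    prioritization cascade and biomarker screening workflow for ovarian
    tumors of four aggressiveness classes (borderline tumors with and
    without the BRAF V600E variant, low-grade and high-grade carcinomas).
    Provides per-region coverage exclusion, allele-fraction and quality
    gates, SNP/non-SNP partitioning, functional-annotation retention
    rules, gene-level binarization with chi-squared/Fisher group
    contrasts, matched univariable/multivariable Cox and logistic
    biomarker screening with bootstrap cross-validated AUC,
    time-dependent ROC with Youden cutoffs and Kaplan-Meier
    stratification, plus a seeded synthetic-cohort generator so the
    whole cascade is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
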