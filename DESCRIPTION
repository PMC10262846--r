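Package: tsmr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (TSMR) toolkit for
    GWAS summary statistics: instrument selection (genome-wide significance
    filtering, greedy LD clumping, F-statistic strength filtering), allele
    harmonization with palindromic-variant inference and proxy lookup, five
    causal-effect estimators (inverse-variance weighted, MR-Egger, weighted
    median, simple mode, weighted mode), heterogeneity and pleiotropy
    diagnostics (Cochran's Q, Egger intercept, leave-one-out, single-SNP),
    an MR-PRESSO global/outlier/distortion test with outlier-corrected
    re-estimation, and prioritization of candidate functional instrument
    variants by combining single-SNP effects with sequence-class perturbation
    scores. Includes a synthetic summary-statistics generator with known
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
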