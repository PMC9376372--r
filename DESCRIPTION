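Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Screens many GWAS exposures against a disease outcome with
    two-sample Mendelian randomization. Provides instrument selection
    (genome-wide significance and minor-allele-frequency filtering, greedy
    LD clumping, proxy-SNP lookup, F-statistic weak-instrument filtering),
    allele harmonization with palindromic-SNP handling, a causal-estimator
    suite (Wald ratio, inverse-variance weighting, MR-Egger, weighted
    median, mode-based estimators, MR-PRESSO), Steiger directionality and
    binary-outcome power diagnostics, false-discovery-rate screening, and
    a synthetic GWAS summary-statistics generator with known ground truth
    so the whole pipeline can be exercised and validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
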