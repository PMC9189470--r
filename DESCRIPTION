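Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complete two-sample Mendelian randomization workflow for GWAS
    summary statistics: instrument selection (genome-wide significance
    filtering, LD clumping, minor-allele-frequency filtering, proxy lookup),
    allele harmonization with palindromic-SNP handling, four causal
    estimators (fixed-effect and multiplicative-random-effects inverse
    variance weighted, MR-Egger, weighted median, weighted mode),
    heterogeneity and horizontal-pleiotropy diagnostics (Cochran's Q,
    Rucker's Q', Egger intercept, MR-PRESSO global/outlier/distortion
    tests), leave-one-out influence analysis, flowchart-based primary-method
    selection, instrument-strength statistics (F, I2-GX), binary-outcome
    power calculation, odds-ratio scaling and report generation, together
    with a synthetic summary-statistics generator with known ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0), yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
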