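Package: mrdiv
Title: Two-Sample Mendelian Randomization Across Diverging Outcome Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Summary-statistics two-sample Mendelian randomization with an
    emphasis on comparing causal estimates across outcome datasets that
    measure the same disease differently (clinically diagnosed GWAS versus
    family-history proxy GWAX). Provides instrument selection and allele
    harmonization for flat GWAS summary tables, per-variant Wald ratios,
    inverse-variance weighted, weighted median and MR-Egger estimators,
    a simulation-based residual-sum-of-squares outlier screen (MR-PRESSO
    style global and per-variant tests), per-variant Cochran's Q / I-squared
    heterogeneity between datasets with a paired t test of Wald estimators,
    a full-pipeline driver, and a synthetic summary-statistics generator
    with recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), metafor, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
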