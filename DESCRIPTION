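Package: polytail
Title: Polygenic Scores and Inference in the Tails of a Trait Distribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for asking whether common-variant polygenic effects explain
    phenotype extremes. Computes weighted allele scores from GWAS summary
    statistics, closed-form expected odds ratios for tail-ascertained
    allelic association under a truncated-normal polygenic model, and
    per-SNP association (stratified Cochran-Mantel-Haenszel, logistic
    regression, inverse-variance meta-analysis). Includes an
    ascertainment-mimicking polygenic cohort simulator with rare-variant
    extensions, replicate-based null distributions of the mean weighted
    allele score with stratified tail tests and rare-variant scenario
    comparison, and a regression-to-the-mean analysis for siblings of
    extreme probands.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
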