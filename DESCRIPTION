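Package: iqsreg
Title: Predicting Genotype Imputation Quality with Nu-Support Vector
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the imputation quality score (IQS), the Cohen's kappa
    statistic applied to the cross-classification of imputed versus true
    genotypes, together with its components the observed agreement (Po) and
    the chance agreement (Pc). Derives a twelve-feature descriptor for each
    imputed SNP (position, allele frequencies, reference-panel genotype
    ratios, distances to the nearest typed SNP and recombination hotspot,
    hotspot recombination rate, and posterior-probability summaries) and
    fits a nu-support vector regression with a radial basis function kernel
    that predicts IQS, Po, or Pc for SNPs whose true genotypes are unknown.
    Includes platform-masking scenario evaluation with mean squared error,
    Pearson correlation, and ROC/AUC false-positive filtering, a synthetic
    scenario generator (haplotype reference panel with hotspot-concentrated
    recombination, mosaic study genotypes, and a surrogate imputer), and
    readers and writers for Beagle-style genotype probability and dosage
    files, truth and annotation tables, and HapMap-style recombination maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
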