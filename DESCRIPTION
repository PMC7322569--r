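Package: grsct
Title: Clumping-and-Thresholding Genetic Risk Scores with Simulated
    Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction and cross-cohort evaluation of genetic risk
    scores (GRS) for a polygenic disease and its severity sub-phenotype.
    Implements PLINK-1 fileset input/output, variant and sample quality
    control, per-SNP association with principal-component covariates,
    genomic inflation, fixed-effects meta-analysis, greedy LD clumping
    over a P-value/r-squared/window grid, allele harmonization and
    weighted scoring with MHC tag-SNP augmentation, a polarized binned
    Z-score polygenicity test, ROC/AUC machinery with DeLong inference,
    quintile odds-ratio stratification of severity, age-of-onset models,
    and an allelic case-control power calculator.  A liability-threshold
    cohort simulator with haplotype-copying linkage disequilibrium,
    Balding-Nichols ancestry drift, and a genetic-load-linked severity
    and onset model makes the full pipeline testable without external
    genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
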