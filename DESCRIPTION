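Package: gmdrPRS
Title: Epistasis Search, Polygenic Risk Scores and Gene-Environment
    Interaction Analysis for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for gene-gene and gene-environment analysis of binary
    case-control cohorts: SNP-level quality control (call rate, minor
    allele frequency, exact Hardy-Weinberg test, heterozygosity),
    covariate-adjusted logistic genome-wide association screening,
    D-prime based linkage-disequilibrium pruning with EM haplotype
    frequency estimation, a from-scratch generalized multifactor
    dimensionality reduction (GMDR) engine with balanced accuracy,
    ten-fold cross-validation consistency and signed-rank model
    selection, risk-allele-count polygenic risk scores with categorical
    stratification, stratified adjusted odds ratios with interaction
    likelihood-ratio tests, and a simplified dietary inflammatory index.
    A synthetic-cohort generator with Hardy-Weinberg genotypes, planted
    epistatic penetrance effects and planted score-by-exposure
    interactions makes every stage testable without access to protected
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2),
    S4Vectors,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
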