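# gmdrPRS

Gene–gene and gene–environment analysis for case-control cohorts with a
rare binary outcome, built around the pipeline used in nutritional
genomics studies of gastric cancer: SNP-level quality control, a
covariate-adjusted logistic GWAS screen, D′-based linkage-disequilibrium
pruning, a from-scratch **generalized multifactor dimensionality
reduction (GMDR)** search for epistatic SNP combinations, a
risk-allele-count **polygenic risk score (PRS)** with low/medium/high
categories, stratified adjusted odds ratios with interaction tests, and
a simplified **dietary inflammatory index (DII)**.

It is intended for biostatisticians and genetic epidemiologists who want
a tested, reproducible implementation of this workflow — and, because
cohort data of this kind are usually access-controlled, it ships a
synthetic-cohort generator that plants known epistatic and
gene–environment effects so every stage can be validated against ground
truth.

## The methods in brief

- **Quality control.** Per SNP: call rate ≥ 96 %, minor allele frequency
  (MAF) > 0.01, and an exact Hardy–Weinberg equilibrium (HWE) test
  p > 0.05 computed from the conditional (Levene–Haldane) distribution
  of the heterozygote count. Per-sample heterozygosity (< 30 %) is
  reported and optionally enforced.
- **GWAS screen.** For each SNP an additive (0/1/2) dosage term is added
  to a covariate-only logistic model; the per-allele odds ratio (OR),
  Wald 95 % CI and p-value are recorded, screened at α = 5 × 10⁻⁴.
- **LD pruning.** Haplotype frequencies are estimated by EM from
  unphased genotype pairs; D′ = |D|/D_max. Among any pair with
  D′ ≥ 0.4 the SNP with the larger association p is removed.
- **GMDR.** Score residuals sᵢ = yᵢ − p̂ᵢ from the null (covariate-only)
  logistic model are pooled within multilocus genotype cells; a cell is
  high-risk iff Σs > 0. Balanced accuracy BA = (sensitivity +
  specificity)/2 is computed on training and held-out folds (TRBA /
  TEBA) under stratified 10-fold cross-validation; every k-SNP
  combination is evaluated, the per-k model is the modal fold-best
  combination with its cross-validation consistency (CVC), and the
  overall best model minimises the exact Wilcoxon signed-rank p of its
  fold TEBAs against 0.5.
- **PRS.** The risk allele of each best-model SNP is the allele with
  OR > 1; each genotype contributes 0/1/2 risk alleles (e.g. TT/GT/GG →
  0/1/2 when G is the risk allele) and the PRS is the sum, categorized
  either at fixed cuts (0–6 / 7–8 / ≥9 for eight SNPs) or by empirical
  tertiles.
- **Gene–environment analysis.** Lifestyle exposures are dichotomized at
  field cutoffs (WBC < 4 × 10⁹/L, coffee < 3 g/day, smoking non vs
  former + current, macronutrient En% cutoffs); within each stratum,
  adjusted ORs by PRS category are estimated against the low-PRS
  reference, and the interaction p comes from a likelihood-ratio test of
  the PRS × stratum product terms.
- **DII.** DII = Σ(component score × daily intake)/100 over a
  38-component table (a synthetic placeholder table ships for testing).

## Worked example

Simulate a cohort with a planted epistatic pair
(`rs12693006` + `rs58499534`, four-fold odds contrast between
neighbouring genotype cells) and run the pipeline:

```r
library(gmdrPRS)
ce  <- simulateCohort(defaultCohortConfig(), seed = 7,
                      design = "balanced", nCase = 400, nControl = 1600)
gw  <- gwasScan(ce, covariates = c("age", "sex", "bmi"))
kept <- ldPrune(dprimeMatrix(ce), setNames(gw$p, gw$snp))
gm  <- gmdrSearch(ce, kept, kRange = 2:3,
                  covariates = c("age", "sex"), seed = 7)
gm
#> GMDRResult: 165 combinations evaluated, 10 folds
#>   best model: rs1045653 + rs12693006 + rs58499534
#>   TRBA 0.6595, TEBA 0.6509, CVC 10/10, signed-rank p 0.001953
```

The search recovers the planted pair (plus the strongest additive SNP,
`rs1045653`) with full cross-validation consistency: the same model is
fold-best in all 10 folds, and its held-out balanced accuracy (0.65) is
well above the chance value 0.5. Building the PRS and testing a
gene–environment stratification:

```r
prs <- buildPRS(ce, bestModel(gm)$snps, gw, cutPoints = "tertile")
lab <- dichotomize(colData(ce)$wbc, stratumPreset("wbc"))
tab <- stratifiedOR(cohortOutcome(ce), prsCategory(prs), lab)
as.data.frame(tab)[, 1:8]
#>   stratum    prs    n cases    or ciLow ciHigh        p
#> 1     low    low  157    23 1.000    NA     NA       NA
#> 2     low medium   59    13 1.647 0.771   3.51 1.97e-01
#> 3     low   high   29     3 0.672 0.188   2.40 5.41e-01
#> 4    high    low 1034   173 1.000    NA     NA       NA
#> 5    high medium  521   151 2.031 1.582   2.61 2.77e-08
#> 6    high   high  200    37 1.130 0.763   1.67 5.42e-01
metadata(tab)$interactionP
#> [1] 0.688
```

Each row is one stratum × PRS-category cell: the OR compares that
PRS category with the within-stratum low-PRS reference after
adjustment; here no PRS × WBC interaction was planted and the
likelihood-ratio interaction p (0.69) is correspondingly unremarkable.

`runPipeline()` chains all stages from a YAML configuration and writes
per-stage TSV/JSON outputs plus a reproducibility manifest.

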