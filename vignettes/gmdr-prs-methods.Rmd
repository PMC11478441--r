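---
title: "Methods: GMDR epistasis search, risk-allele PRS and gene-environment analysis"
author: "gmdrPRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GMDR epistasis search, risk-allele PRS and gene-environment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmdrPRS)
```

## Scope and data model

gmdrPRS implements the analysis chain used in polygenic studies of a
rare binary disease in a large observational cohort: genotype quality
control, a covariate-adjusted logistic screen, linkage-disequilibrium
(LD) pruning, a generalized multifactor dimensionality reduction (GMDR)
search for epistatic SNP combinations, a risk-allele-count polygenic
risk score (PRS), and stratified gene-environment odds-ratio analysis
with an interaction test, plus a simplified dietary inflammatory index
(DII).

The central container is `CohortExperiment`, a
`SummarizedExperiment` with one `"dosage"` assay (SNP × sample
minor-allele counts 0/1/2, `NA` for missing calls), SNP metadata in
`rowData`, and the binary `outcome` plus covariates/exposures in
`colData`. Simulated cohorts carry a truth record of planted effects in
`metadata()`. The package surface groups into the simulator
(`R/simulate.R`), QC and LD (`R/qc.R`), the logistic engine and GWAS
scan (`R/association.R`), the GMDR engine (`R/gmdr.R`), PRS
(`R/prs.R`), gene-environment and DII (`R/gxe.R`) and file/pipeline
I/O (`R/io.R`).

## The synthetic cohort generator

Because cohort data of this kind sit in access-controlled biobanks, the
generator is a first-class, tested module, not a fixture. It emulates a
Korean urban-hospital health-examinee cohort:

* **Genotypes.** Unlinked SNPs are Binomial(2, MAF) draws —
  Hardy–Weinberg equilibrium (HWE) by construction. An LD-partnered SNP
  is drawn jointly with its partner from the two-locus haplotype
  distribution implied by the two MAFs and a target D′ (each sample
  receives two independent haplotypes); an infeasible D′ raises a
  parameter error. Missing calls are injected completely at random at a
  configurable per-SNP rate, default 0 (post-QC cohort missingness is
  not reported in this literature, so the clean default is assumed).
* **Exposures.** White blood cell count ~ N(5.7, 1.55²) ×10⁹/L, energy
  intake (percent of estimated need) ~ N(98.7, 31.5²), macronutrient
  energy fractions, smoking status (non/former/current) at
  (0.73, 0.16, 0.11), coffee g/day as a zero-inflated gamma, plus age,
  sex, BMI, residence, exercise, education and income — values anchored
  to the descriptive statistics such cohorts report. Every distribution
  is overridable.
* **Outcome.** A single logistic data-generating model: η = intercept +
  additive per-allele log-ORs + 3×3 epistasis cell offsets + covariate
  terms + gene-environment products (risk-allele-count score ×
  exposure); y ~ Bernoulli(expit η). Epistasis is planted as cell-level
  *log-odds offsets* rather than penetrance probabilities so additive
  and epistatic parts compose in one η, matching the logistic analysis
  downstream. `checkerboardCells(beta)` plants a near-pure epistatic
  pattern (offset where the two dosages have odd sum) with weak
  marginal effects at intermediate MAFs.
* **Scale.** `defaultCohortConfig()` is a one-tenth-scale template of
  the motivating study: 4,830 samples, baseline prevalence 0.6 %, ten
  unlinked SNPs at the MAFs of a published ten-variant gastric-cancer
  panel, a planted checkerboard pair on the two strongest variants.
  `design = "balanced"` draws batches from the same population model
  until requested case/control quotas are met (retrospective sampling).
  Rare-outcome realism and test power pull in opposite directions;
  tests use the balanced design where power matters.

All draws come from one stream per (stage, seed) with a documented
order (genotypes in spec order, then exposures, then the outcome), so
identical configuration and seed reproduce the cohort bit for bit,
including injected missingness. What the generator does **not** emulate:
population stratification, relatedness, haplotype blocks beyond pairwise
D′, genotyping-intensity artefacts, and exposure–exposure correlation
structure. Passing tests therefore demonstrate correctness of the
*methods*, not robustness to those real-data complications.

## Quality control

A SNP is kept iff call rate ≥ 1 − 0.04, MAF > 0.01 and exact HWE
p > 0.05 (defaults in `qcThresholds()`). The HWE test enumerates the
conditional distribution of the heterozygote count given the allele
counts and sums the probabilities of tables no more probable than the
one observed; monomorphic tables return p = 1 and the test is exact for
any sample size. Genotyping accuracy (an intensity-level criterion on
the original arrays) cannot be recomputed from dosages and is
approximated by call rate alone.

The 30 % *heterozygosity* criterion is applied per **sample**, not per
SNP: under HWE a SNP with MAF 0.3 has an expected heterozygote fraction
of 0.42, so a per-SNP threshold of 0.30 would discard most common
variants — including the very panel this class of study reports. The QC
report carries per-SNP heterozygote fractions and a per-sample
heterozygosity table flagged at the threshold; sample exclusion is
opt-in (`excludeHetSamples`), since on a small simulated panel the
per-sample fraction is a noisy version of a statistic meant for
genome-wide arrays.

## LD estimation and pruning

`estimateDprime()` estimates haplotype frequencies by EM over the nine
unphased two-locus genotype classes. Only the double heterozygote has
ambiguous phase; its cis/trans split is re-estimated from the current
frequencies each iteration until the largest change is below 1e-8
(capped at 1000 iterations). D′ = |D|/D_max is invariant to allele
relabeling and clamped to [0, 1]; monomorphic input raises an error
rather than returning a number.

The pruning rule reads "exclude strongly linked SNPs" as: retain a set
whose pairwise D′ is everywhere *below* 0.4. Greedy resolution: among
the currently worst pair at or above threshold, the SNP with the larger
screening p-value is removed (the next stage consumes
association-screened SNPs, so the better-supported SNP should survive);
exact ties keep the SNP earlier in genomic order.

## The logistic engine and the GWAS screen

`fitLogistic()` wraps binomial iteratively-reweighted least squares
(tolerance 1e-10, ≤ 100 iterations) and adds observed-information
standard errors, the log-likelihood, and quasi-separation detection
(|β| > 20 or SE > 100 flags the fit non-converged; downstream functions
refuse flagged fits instead of printing numbers from them). Wald ORs
use exp(β ± 1.96·SE); nested models are compared by likelihood-ratio
tests.

The scan codes genotypes additively (0/1/2 minor-allele dosage) — the
standard GWAS convention, and the one consistent with risk-allele
counting afterwards. Covariates are handled complete-case; two named
presets reflect the two covariate lists such studies quote
(`covariateSet("set1")` for the screening stage,
`covariateSet("set2")` adding lifestyle terms for the modelling stage)
— the package exposes both rather than guessing which applied where.
The screening α defaults to 5 × 10⁻⁴ (a deliberately liberal
Bonferroni-style cutoff for a rare outcome); no genomic-control
correction is applied. SNPs monomorphic on the analysed rows, or with
flagged fits, are skipped with a recorded reason.

## The GMDR engine

Score residuals sᵢ = yᵢ − p̂ᵢ come from the null logistic model
(covariate-only; intercept-only reduces to yᵢ − ȳ). With an intercept
the scores sum to zero, which motivates the cell threshold **T = 0**: a
multilocus cell is high-risk iff the sum of its members' scores is
positive, i.e. iff the cell's (covariate-adjusted) observed risk
exceeds the baseline. For k = 1 without covariates this is exactly the
sign of the cell's case-fraction excess — an identity the tests assert.
Cells never observed in training are labeled low-risk: conservative, as
there is no training evidence of elevated risk.

Cross-validation is stratified by case status (at 0.6 % prevalence,
unstratified folds can lose every case) with fold sizes differing by at
most one per class. Per fold, cells are labeled on the training 9/10
and applied to the held-out 1/10; balanced accuracy — robust to the
heavy class imbalance — is recorded as TRBA (training) and TEBA (test).
The fold-best combination is the one with the highest training balanced
accuracy in that fold; per k, the selected model is the modal fold-best
combination and CVC is the number of folds choosing it (ties broken by
higher mean TEBA, then lexicographically smallest SNP set, making the
search invariant to enumeration order). The overall best model
minimises the exact signed-rank p of its fold TEBAs against 0.5, with
ties broken by CVC then TEBA. Samples missing a genotype at a
combination's SNPs are dropped for that combination only. An explicit
combination budget guards the exhaustive search.

The signed-rank p is reported for both TRBA and TEBA folds (the
literature's phrasing is ambiguous about which); model selection uses
TEBA's p, the held-out quantity. A known limitation, demonstrated by
the calibration tests: because the tested model is *selected* (modal
fold-best among many combinations), its fold TEBAs are not a null
sample — chance association that makes a combination fold-best is a
property of the pooled data and shifts every fold's TEBA the same way.
The signed-rank p of the selected model is therefore anticonservative
under the global null, which is why practice combines it with a strict
threshold (e.g. p < 0.001) and a high CVC rather than reading it as a
calibrated 5 % test. For a *prespecified* combination the engine is
calibrated (held-out balanced accuracy centres on 0.5).

## PRS construction

The risk allele of each model SNP is the allele whose additive dosage
carries OR > 1 (the coded minor allele if OR > 1, otherwise the major
allele); OR exactly 1 is an error, not a silent choice. Per SNP a
genotype contributes its risk-allele count 0/1/2, and the PRS is the
integer sum over model SNPs (range [0, 2k]). Samples missing any model
genotype are excluded and flagged by default — imputation would break
the integer semantics — with mean-dosage imputation available behind
`missingPolicy = "meanImpute"`. Categorization offers empirical
tertiles (type-1 quantiles, ties to the lower category) as the general
mode and fixed cuts (6, 8) — low 0–6, medium 7–8, high ≥ 9 for an
eight-SNP score — as the replication preset `"gc8"`; published group
sizes under these cuts are visibly not exact tertiles, which is why
both modes exist and report their realized group sizes.

## Gene-environment analysis and the DII

Exposures are dichotomized with strict `<` cutoffs (WBC < 4 × 10⁹/L,
coffee < 3 g/day, energy below estimated need, carbohydrate < 65 En%,
protein < 13 En%, fat < 20 En%); smoking pools former with current
against never. Within each stratum, ORs by PRS category are estimated
against the **within-stratum** low-PRS reference (the natural reading
when every stratum row shows a reference of 1); a pooled-reference
variant sits behind `reference = "pooled"` since the phrasing in the
literature admits both. Empty or separation-flagged cells are marked
inestimable rather than fabricated.

The interaction test is a logistic likelihood-ratio test of the
PRS × stratum product terms on (categories − 1)(levels − 1) degrees of
freedom — chosen over a two-way ANOVA on incidence because the outcome
is binary and this stays inside the same OR machinery; an ANOVA-style
cell-means incidence report (`cellIncidence()`) is emitted alongside
for descriptive comparability. No multiple-testing correction is
applied across stratifiers (reported as-is, as in the motivating
literature).

The simplified DII is Σ(component score × daily intake)/100. The
38-component inflammatory score table is a user-supplied parameter; the
shipped `dii_scores_synthetic.tsv` is a synthetic placeholder (real
analyses must substitute published scores), and `computeDII()` refuses
components without a score by name.

## Numerical choices and problem sizes

EM tolerance 1e-8; IRLS tolerance 1e-10, 100 iterations; separation
flags at |β| > 20 / SE > 100; exact signed-rank distribution for the
10-fold vectors (ties fall back to the usual approximation with a
warning); all tie-breaks deterministic and order-invariant. The test
suite validates calibration at the sizes a desk machine handles
comfortably: HWE against brute-force enumeration for every table with
n ≤ 50; D′ recovery at n = 50,000; GWAS null uniformity on 500 SNPs at
n = 5,000; GMDR power on 2,000 + 2,000 balanced cohorts; interaction
type-I error over 200 null replicates at n = 5,000. These sizes are the
package's chosen study conditions for its own validation and are stated
in the tests themselves.

## Known limitations

Pairwise D′ only (no haplotype blocks or r²-based pruning); no
population-structure or relatedness modelling; no weighted or
shrinkage PRS (risk-allele counting only); the signed-rank significance
of a *selected* GMDR model is anticonservative, as discussed; the DII
placeholder scores are synthetic; and real-data replication of any
published cohort's ORs requires that cohort's data, which this package
deliberately does not depend on.
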