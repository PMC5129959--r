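---
title: "Methods: small RNA and ceRNA network analysis of tumor spread types"
author: "ceRNAspread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA and ceRNA network analysis of tumor spread types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAspread)
suppressMessages(library(SummarizedExperiment))
```

# Scope and scientific setting

High grade serous ovarian cancer (HGSOC) spreads through the peritoneum in
two macroscopically distinct patterns: *miliary* (innumerable millet-sized
implants, worse prognosis) and *non-miliary* (few large, bulky implants).
This package implements a complete, testable analysis pipeline for comparing
the two spread types from matched small RNA and rRNA-depleted RNA
sequencing of enriched tumor cells sampled from up to four tissue origins
per patient — primary ovarian tumor (P), peritoneal metastasis (M), ascitic
single cells (A) and ascitic spheroids (S):

* count normalization (log-CPM and cyclic loess) and abundance filtering;
* per-feature differential expression with a tissue-origin confounder;
* the combined **gene-miR set** analysis: assigning miRNA regulators to gene
  sets by Fisher's exact test and testing joint, direction-aware
  deregulation;
* global **ceRNA network** statistics: a circRNA back-splice index and
  abundance ratios of RNA classes;
* the **13 sRNA spread predictor** (a difference of median expressions) and
  its median dichotomization;
* Cox proportional-hazards modeling with **risk-transfer validation**.

Because no patient-level data are distributed, a synthetic cohort generator
with planted, recoverable effects is a first-class module: every downstream
claim the test suite makes is demonstrated on data whose ground truth is
known.

# Normalization

Raw counts are transformed to
$\log_2\!\big((\text{count} + 0.5) / (\text{library reads}/10^6)\big)$,
log-CPM with a 0.5-read offset. Library sizes are the total library read
counts fixed at object construction, so the abundance filter does not change
the scale of retained features. Two details deserve note:

* **Filtering** keeps features with *strictly more than* 100 supporting
  reads summed over all samples (a row-sum of exactly 100 is removed), and
  precedes normalization: the inclusion rule defines the analyzed feature
  set.
* **The 0.5 offset** breaks exact invariance to joint rescaling of counts
  and library sizes; the discrepancy is $\mathcal{O}(1/\text{count})$ and
  negligible above a few hundred reads. The tests treat this invariance as
  asymptotic, not exact.

Cyclic loess normalization removes smooth intensity-dependent biases
between samples: for each sample pair, a loess trend of the log-ratio (M)
against the average log-intensity (A) is fitted and half subtracted from
each member, cycling over all pairs. We use span 0.7 and 3 iterations —
common practice for the method, exposed as arguments — and delegate the
computation to `limma::normalizeCyclicLoess()`. A `method = "fast"` option
(each sample against the mean) is available for large simulation sweeps,
where the pairwise method's quadratic cost in sample number is wasteful.
IsomiR collapsing is supported through an explicit user-supplied
feature-to-group map (`collapseFeatures()`); the package deliberately does
not define sequence similarity, which is out of scope.

Whether small RNA classes should be normalized jointly or per class is not
prescribed; the default is joint normalization of the whole matrix, and a
per-class analysis can be assembled by subsetting before normalization.

# Differential expression

Each feature is fitted by ordinary least squares,
$y = \beta_0 + \gamma\,\text{tissue} + \beta\,\text{group} + \varepsilon$,
on normalized log expression; the reported statistic is the $t$ of the group
coefficient (log2 fold change, group 1 minus group 0) with two-sided
p-values and Benjamini–Hochberg adjustment (`bhFDR()`, FDR < 5% is the
package-wide significance convention). Without a confounder this reduces
exactly to the pooled-variance two-sample t-test. OLS was chosen over a
moderated (empirical-Bayes) variance because it is fully specifiable and
exactly testable against hand computation; with the feature counts and
effect sizes used here moderation changes little.

A caveat the synthetic generator makes visible: samples of one patient
share biological random effects, so sample-level OLS across spread types
(a patient-level label) is anticonservative when several tissue origins per
patient enter one comparison. The paper-style analysis accepts this (tissue
origin enters as a fixed confounder, not the patient); the calibration
property tests therefore use single-tissue cohorts, where samples are
independent. Conclusions from multi-tissue comparisons should lean on the
signature and set-level machinery rather than single-feature p-values.

# Gene-miR sets

A *gene-miR set* couples a gene set with its putative miRNA regulators:

1. **Assignment** (`assignMiRsToGeneSet()`): for each miRNA with verified
   targets, the 2×2 table (in-set targeted / in-set non-targeted /
   out-of-set targeted / out-of-set non-targeted) is tested one-sided for
   enrichment; this is the hypergeometric upper tail
   $P(X \ge a)$, $X \sim \mathrm{Hypergeom}(N, K, n)$. miRNAs with
   $p < 0.05$ form the miR set. The background is the disjoint out-of-set
   complement by default; a switch (`backgroundIncludesSet = TRUE`)
   reproduces the literal "all genes" background reading. The universe is
   the intersection of the target table's genes with the analyzed
   transcriptome — "all genes" must mean genes that could have been
   observed.
2. **Set-level test** (`setDeregulationTest()`): the observed score is the
   mean member $t$ statistic; the null is competitive, built by drawing
   equally sized random feature sets, with an add-one two-sided permutation
   p-value. A score of exactly zero is labeled "up" (fixed tie convention).
   The published analysis used QuSAGE for this step; its internals are not
   reproducible from the description, so this package substitutes the
   permutation test, whose null is exactly specifiable — a documented
   methodological deviation, not an approximation of QuSAGE.
3. **Combination**: Fisher's method,
   $-2(\ln p_{\text{gene}} + \ln p_{\text{mir}}) \sim \chi^2_4$, followed by
   BH adjustment of the combined p-values across sets (per comparison).
4. **Concordance** (`concordanceSummary()`): along a cutoff grid on the
   adjusted combined p-value, the percentage of sets deregulated in
   opposite directions and, within those, the percentage with gene set down
   and miR set up — the pattern expected if miRNAs suppress their targets.
   Cutoffs with no qualifying sets report missing values, not zeros.

Under a global null, BH-adjusted q-values below 5% are rare by
construction; the ~5% calibration statement applies to the raw combined
p-values, and the tests check exactly that.

# ceRNA network statistics

* `circIndex()`: back-splice events divided by all (back + linear) splice
  events per sample — depth-invariant, in $[0, 1]$. Events are read counts;
  distinct-junction counting would be a caller-side aggregation choice.
* `ncCodingRatio()`: median lncRNA expression over median coding
  expression, medians on the linear scale ($2^{\log}$) so the ratio reads
  as an abundance ratio; a log-scale option exists.
* `mirAbundanceRatios()`: total raw miRNA reads normalized to snRNA or
  snoRNA totals, and the miRNA / long-linear-RNA ratio under either
  normalizer (algebraically identical when both normalizers are positive —
  kept as separate columns because each mirrors a reported panel).
* `compareGroups()`: pooled-variance Student t-test between spread types on
  any per-sample statistic.
* `meanExpressionBySpread()`: per-gene means within tissue class (PM / AS)
  and spread type, compared per biotype with a paired t-test across genes —
  the gene-wise global comparison; the sample-level panels use the Student
  t-test above.

# Spread predictor

The signature holds miliary-up and non-miliary-up member lists; the score
of a sample is $\mathrm{median}(\text{up}) - \mathrm{median}(\text{down})$,
interpreted relatively (higher = more miliary-like). The shipped default
(`defaultSpreadSignature()`) carries the 13 published members: 3 miliary-up
miRNAs and 10 non-miliary-up sRNAs (8 miRNAs, 2 piRNAs). Cohort calls are
made by a median split, ties falling to non-miliary (fixed convention).
`selectSignature()` operationalizes the "robust, not model driven"
derivation as a threshold-and-direction filter: members must be FDR-
significant in the primary-tumor (P) comparison and non-significant in
*every* other supplied comparison, and at least two candidates per
direction are required. The score is location-invariant, so RT-qPCR
$-\Delta C_q$ values can be scored interchangeably with sequencing-derived
log expression.

# Survival and transfer validation

Cox models are fitted by `survival::coxph()` with Breslow tie handling
(Efron via an argument) behind `fitCoxModel()`, which returns a
`CoxModelFit` holding coefficients, covariance, and Wald 95% intervals;
hazard ratios are `exp(coef)` exactly, and HR intervals are `exp` of
coefficient intervals. Monotone likelihoods (perfect separation) are
rejected with a diagnostic rather than returned with divergent estimates.
FIGO stage enters as a single ordinal 0/1/2 term (II/III/IV), matching one
printed coefficient.

The published training model (165 patients, 78 events; age 0.38, FIGO
1.02, residual tumor 0.70, grade 0.54, spread predictor 0.56) ships as
`trainingSpreadModel()`, with a diagonal covariance reconstructed from the
printed confidence intervals — the off-diagonals are simply not
recoverable from a table, which only matters for joint Wald tests the
package does not perform.

**Transfer validation** (`validateTransfer()`): the training model's linear
predictor is computed for each validation subject and entered as the single
covariate of a Cox model fitted on the validation cohort's survival; the
calibration slope should be 1, and validation passes when its CI95 covers
1. Doubling all training coefficients halves the expected slope — the
algebra the tests verify by simulation. `hrWithinCI()` implements the
complementary check that a validation-cohort hazard ratio falls inside the
training CI95.

# Synthetic cohorts

`generateCohort()` draws negative-binomial counts (common dispersion 0.2;
variance $\mu + \phi\mu^2$) around biotype-specific baseline abundances
(relative library mass: miRNA 0.40, coding 0.35, lncRNA 0.10, piRNA 0.10,
snoRNA 0.03, snRNA 0.02 — a small-RNA-dominated library with an
rRNA-depleted long fraction). Defaults mirror the modeled study: 23
patients (11 miliary / 12 non-miliary), four tissue origins each, mean
library 14.2 million reads with log-normal spread 0.25 (median depth range
roughly 10–25 million). Between-patient biological variation (log2 SD
0.25, drawn per patient × feature) is shared across each patient's ascitic
and solid samples, inducing the within-patient correlation of repeated
measures. Planted effects, echoed in `$truth`:

* miliary solid samples: lncRNA log2 shift (default −1) and a back-splice
  rate shift on the logit scale (default −0.5, baseline rate 0.1);
* designated up-miRNAs (default 20) move by $-\text{mirnaTargetLogFC}$
  while their verified coding targets move by $\text{mirnaTargetLogFC}$
  (default −1): one knob plants "miRNAs up, targets down";
* a planted 13-member signature (±2 log2 by spread type);
* survival: exponential event times with log-hazard equal to the planted
  coefficient effects (defaults: the published training coefficients, the
  spread type entering as the predictor covariate), baseline median 45
  months, and uniform administrative censoring whose horizon is solved
  numerically so the expected censored fraction matches the target
  (default 87/165, reproducing ~78 events in a cohort of 165).

What the generator does **not** emulate: sequence-level isomiRs, read-level
noise, miRNA–target correlation structure beyond planted mean shifts,
non-proportional hazards, informative censoring, and batch effects.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to every artifact of real
sequencing data.

# Numerical choices and degenerate inputs

* Permutation p-values use the add-one estimator (never exactly zero);
  Fisher-combined zero p-values are clipped at $10^{-300}$ with a warning.
* Degenerate variance: identical groups return $t = 0$, $p = 1$; all-equal
  predictor scores make a median split meaningless and are refused.
* Set scores of exactly 0 are "up"; predictor ties at the median are
  non-miliary; both conventions are arbitrary but fixed.
* Cox fits reject perfect separation, empty event sets, and collinear
  covariates with diagnostics.
* Seeds: every stochastic routine accepts a seed; identical inputs and
  seeds give byte-identical cohorts and permutation p-values.

# Problem sizes used by the test suite

Simulation-based checks are sized to demonstrate each property with
comfortable statistical margins while keeping the default suite quick:
cohorts of 10–30 patients with a few hundred features per run; 200
replicates for Cox recovery and transfer calibration at $n = 165$; 100
replicates for the ceRNA depletion pattern; 400 null and 200 planted
gene-miR sets at 499 permutations; the Fisher-assignment oracle sweep
covers every hypergeometric table with a universe up to $N = 60$. The
acceptance script uses 400 survival replicates. Hazard-ratio recovery is
summarized on the log scale (geometric mean across replicates): the
arithmetic mean of $\exp(\hat\beta)$ is upward-biased by Jensen's
inequality at realistic event counts and does not estimate
$\exp(\beta)$.

# Worked example

```{r example}
cohort <- generateCohort(cohortConfig(nPatients = 12, nCoding = 400,
                                      nLncRNA = 150, nMiRNA = 200,
                                      nPiRNA = 60, nSnRNA = 20,
                                      nSnoRNA = 20, libSizeMean = 5e5,
                                      nGeneSets = 40, seed = 8))
expr <- logCPM(filterMinReads(cohort$counts))
ann <- colData(cohort$counts)

## ceRNA pattern in solid tissue
pm <- ann$tissue %in% c("P", "M")
compareGroups(circIndex(cohort$junctions)[pm], ann$spread[pm])$p
compareGroups(ncCodingRatio(expr)[pm], ann$spread[pm])$p

## spread predictor on the planted signature
score <- spreadScore(expr, cohort$truth$signature)
table(dichotomize(score), ann$spread)

## risk transfer of the published training model
val <- generateSurvival(n = 165, coefficients = coef(trainingSpreadModel()),
                        seed = 9)
validateTransfer(trainingSpreadModel(), val)
```

# Known limitations

* The gene-miR set engine is a permutation test, not QuSAGE; absolute
  significant-set counts are not comparable with the original analysis
  (which is in any case impossible without the patient data).
* The published signature's member *identities* are shipped, but their
  expression cannot be re-derived without the cohort's qPCR data.
* `trainingSpreadModel()` carries no coefficient covariances.
* Sample-level DE p-values are anticonservative under multi-tissue
  within-patient correlation (see above).
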