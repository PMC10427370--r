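---
title: "Methods: cell composition and 5hmC responsiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell composition and 5hmC responsiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcresponse)
```

# Scope

`hmcresponse` implements a bulk-omics analysis of treatment response in
acute myeloid leukemia (AML) cohorts receiving azacitidine (AZA) epigenetic
priming before intensive chemotherapy. The pipeline connects four layers of
evidence:

1. **Differential expression** between responders (complete remission with
   or without count recovery, CR/CRi) and non-responders (treatment
   failure, TF), with co-expression module detection and gene-set
   enrichment.
2. **Digital cytometry**: bulk expression profiles are decomposed into six
   malignant AML subsets (HSC-like, Prog-like, GMP-like, ProMono-like,
   Mono-like, cDC-like) and seven immune populations (B, cDC, CTL,
   Monocyte, Plasma, T, NK), and the resulting fractions are used as
   response classifiers.
3. **5hmC responsiveness**: paired Day 0 / Day 5
   5-hydroxymethylcytosine profiles quantify each patient's epigenetic
   reaction to AZA as the number of differentially hydroxymethylated genes
   (DhMGs) or the Day5-Day0 Spearman correlation, which then feed survival
   analysis.
4. **A 5hmC response signature**: gradient-boosted trees on rlog 5hmC
   levels with patient-grouped cross-validation, split-count (F score) gene
   ranking, top-k refitting, and shuffled-label controls.

Because the underlying patient data are access-controlled, every stage is
validated on synthetic cohorts with planted ground truth; the generator is
first-class, tested code.

# The synthetic-cohort generator

`sim_config()` fixes the study conditions; the generators never reread
tuning from the analysis side.

**Bulk cohorts** (`generate_bulk_cohort()`). Patient cell-type fractions
are Dirichlet with total concentration 8 and means 0.2 for GMP-like and
HSC-like (the two subsets whose balance carries the response signal), the
remaining mass spread evenly. Per-tissue (BM/PB) sample fractions are
re-drawn around the patient mean with concentration 200, giving the high
between-tissue concordance the analysis relies on. The responder label is
Bernoulli with probability `plogis(response_effect * z)`, where `z` is the
cohort-standardized composite `(GMP - HSC) + NK`; expressing the effect in
per-standard-deviation log-odds keeps its meaning stable across
concentration settings (raw fraction scales would make any stated effect
size essentially uninterpretable, since the composite's SD varies by an
order of magnitude over reasonable concentrations). Counts are negative
binomial (default dispersion 0.05, depth 10^6) around
`expression mixture x gene length`, so that TPM normalization recovers the
linear mixture the deconvolution model assumes. Gene lengths are
log-uniform on 0.5-10 kb and written alongside the counts.

**5hmC cohorts** (`generate_hmc_cohort()`). Each patient's Day 0 profile is
a shared cohort profile (log-normal across genes, sd 1) times a
patient-specific log-normal deviation (sd 0.35). At Day 5 a random gene
subset is shifted by `dhmg_log2_shift` (default 2, random sign); the subset
size is a dose-dependent fraction of the gene universe (defaults 2% / 5% /
10% of genes at 37.5 / 50 / 75 mg/m2), making the DhMG count dose-monotone
by construction. A fixed set of `n_response_genes` (default 30, drawn from
detectably expressed genes) is additionally shifted in responders on both
days — the ground truth for signature selection. Survival is exponential
with log-hazard `log(base_hazard) - survival_hazard_coef x |shifted set|`,
so stronger 5hmC alteration means longer survival; a `censoring_rate`
share of patients is censored uniformly before their event.

What the generator does **not** emulate: mutational genotypes, batch
effects beyond scale factors, gene-gene correlation beyond the mixture
structure, and library-preparation artifacts. Green tests therefore show
the pipeline recovers the planted statistical structure, not that it is
robust to every failure mode of real sequencing data.

# Differential testing

Normalization is median-of-ratios (`size_factors()`), with TPM
(`tpm_normalize()`) for linear-scale work and
`log2(count/size_factor + 1)` (`rlog_approx()`) as a documented
approximation to the regularized log for classifier features.

`nb_wald_test()` tests group B versus A per gene on normalized counts. The
dispersion is estimated by method of moments from the pooled within-group
variance, then shrunk 50/50 in log space toward a trend `a0 + a1/mean`
fitted through binned medians — a deliberately transparent stand-in for
heavier empirical-Bayes machinery that behaves correctly at the 2-vs-2
designs this pipeline uses (paired Day0/Day5 with BM+PB as replicates).
The Wald statistic (log2 fold change over its delta-method standard error)
is referred to a Student t with **three times the residual degrees of
freedom**: the trend shrinkage roughly triples the information in the
dispersion estimate, and the plain normal reference is measurably
anti-conservative at two or three replicates per group. With this
moderation the null rejection rate at p < 0.05 sits inside 0.035-0.065
for 2v2, 5v5 and 10v10 designs (the acceptance suite checks this at 5000
null genes).

Two filters are deliberately distinct:

* DEGs: `padj <= 0.1` **and** `|log2FC| >= 0.5` (BH-adjusted, inclusive);
* DhMGs: raw `p < 0.01` (strict) **and** `|log2FC| >= 0.5`.

Genes with zero counts across the tested samples are dropped (count
recorded). BH adjustment delegates to `stats::p.adjust`; a brute-force
step-up oracle arbitrates it in the tests.

# Deconvolution

The signature matrix selects, per cell type, the top `markers_per_type`
(default 50) genes by fold over the maximum of the other types — a
deterministic, inspectable rule; the condition number is reported, not
optimized. Fractions are estimated per sample by non-negative least squares
in linear TPM space (`pracma::lsqnonneg` on the unit-sum bulk column, which
makes the estimate exactly scale-invariant), then renormalized to
proportions. NNLS replaces the support-vector regression of web-based
digital cytometry: it is deterministic, dependency-light and accurate at
this problem scale; batch correction is out of scope (a per-batch median
scaling can be applied upstream). Malignant and immune compartments are
rescaled to sum to 1 separately (`compartment_normalize()`), and BM/PB
fractions are averaged per patient (`average_tissues()`) — means of simplex
points need no renormalization.

# Enrichment

`preranked_gsea()` implements the weighted Kolmogorov-Smirnov running sum
(hit increments proportional to `|stat|^weight`, default weight 1; misses
decrement `1/(N - Nh)`), with the enrichment score the signed extreme of
the walk. Significance comes from gene-label permutations — the standard
null for preranked inputs; NES divides ES by the mean same-sign null
magnitude, and the two-sided p-value is the sign-matched tail with
resolution `1/(n_perm + 1)`. Ranking ties break deterministically by gene
id. The per-sample score (`sample_set_score()`) is the within-sample mean
rank difference between set and complement divided by N — rank-based,
hence invariant to monotone transforms; it approximates the max-deviation
convention of per-sample enrichment scoring rather than reproducing any
specific package's kernel. Weighted signature scores
(`weighted_signature_score()`) are plain coefficient-weighted sums of
`log2(TPM + 1)`; 17-gene stemness-score weights are supplied by the user
(weighted GMT), not hardcoded.

# Co-expression modules

Pairwise Pearson correlations between differentially expressed genes on
variance-stabilized expression; average-linkage hierarchical clustering of
the Euclidean distances **between correlation-matrix rows** (the
correlation profile, not the raw expression profile — a documented choice
where either reading is defensible), cut at k = 4 by default. Modules are
extended with first-order neighbors from a user-supplied interaction edge
list when the neighbor's mean expression strictly exceeds 3 TPM.

# Classifiers

Composition scores are transparent combinations of patient-level fractions
(GMP - HSC difference; NK + GMP sum — the sum was chosen over a fitted
combination as the simplest reading, with a logistic combination possible
downstream of the exported fractions). ROC/AUC is Mann-Whitney with ties
counted half.

The 5hmC signature model trains gradient-boosted trees (binary logistic;
depth 3, 100 rounds, learning rate 0.1) on rlog 5hmC features with
patient-grouped 5-fold cross-validation: folds partition patients, every
sample inherits its patient's fold, and an assertion plus a hard
`evaluate_test()` guard make patient leakage structurally impossible.
Per-tree column subsampling (`colsample_bytree = 0.1`) is the one
hyperparameter set away from the library default: with thousands of
features and under a hundred samples, a fully greedy booster concentrates
all splits on a handful of genes once the loss saturates, which makes
split-count (F score) rankings of redundant informative sets degenerate;
subsampling spreads splits across the informative genes and stabilizes the
ranking. Importance is the split count of a final all-train fit; top-k
refitting scans a k grid under the same folds and keeps the smallest k at
the maximal cross-validated AUC.

Two AUC summaries are reported: pooled out-of-fold probabilities (the
headline `cv_auc`) and the mean of per-fold AUCs. The shuffled-label
control uses the fold-averaged statistic because the pooled version is
biased below 0.5 under a label-permutation null — fold models' probability
scales anti-correlate with the held-out class balance in small grouped
folds — which would make even a leak-free pipeline look "anti-predictive".

# Survival

Per-patient responsiveness statistics: the DhMG count (NB Wald Day 5 vs
Day 0 on the patient's four samples, BM+PB pooled as replicates) and the
Day5-Day0 Spearman correlation of normalized profiles (BM by default).
Patients split at the median (ties to "low" — the documented rule; the
data decide nothing here). Kaplan-Meier, log-rank and Cox fits delegate to
the `survival` package, with Breslow tie handling chosen for
hand-checkability (Efron available); multivariable models adjust for age
and sex. The acceptance suite pins these wrappers to hand-derived values
(product-limit 2/3 and 1/3; log-rank chi-square 2.882 on the four-record
example; Cox coefficient -ln(2)/2 on the three-record example) and to a
brute-force O-E/V log-rank oracle on random cohorts.

# Problem sizes and numerical choices

Tests and the acceptance script run at desk scale, chosen as the smallest
sizes at which the checked properties are stable: 2000-gene universes,
cohorts of 18-60 patients, 5000 null genes for type-I calibration, 150
random sets for enrichment calibration, 20 label shuffles, and 20
replicates for the survival end-to-end property. Degenerate inputs
(all-tied Wilcoxon data, constant paired differences, zero-mass
compartments, all-zero genes) return the limiting value or fail with a
classed error rather than NaN. All randomness flows from explicit seeds;
generator streams derive deterministic sub-seeds per cohort.

# Known limitations

* The dispersion trend is a two-parameter fit through binned medians, not
  an empirical-Bayes posterior; at a single extreme design (1 vs n) the
  test refuses to run rather than degrade.
* The rlog approximation omits per-gene shrinkage; at very low counts its
  variance is larger than a true regularized log.
* NNLS deconvolution assumes linear mixing in TPM space and shares the
  usual blindness to cell types absent from the reference.
* Survival simulation uses exponential times; no competing risks or
  time-varying effects.
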