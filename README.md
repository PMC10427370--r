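# hmcresponse

Cell composition and 5-hydroxymethylcytosine (5hmC) signatures of response
to azacitidine-primed chemotherapy in acute myeloid leukemia (AML).

## What it is for

Epigenetic priming with azacitidine (AZA) before intensive chemotherapy
helps some high-risk AML patients and not others, and the biology behind
that split is an open question. This package implements, as reusable and
tested R functions, the analysis linking two kinds of molecular evidence to
treatment response:

* **Who responds** relates to *cellular composition*: bulk RNA-seq profiles
  are decomposed (digital cytometry) into six malignant AML subsets
  (HSC-like, Prog-like, GMP-like, ProMono-like, Mono-like, cDC-like) and
  seven immune populations (B, cDC, CTL, Monocyte, Plasma, T, NK).
  Responders (CR/CRi) carry more GMP-like and fewer HSC-like malignant
  cells, and more NK cells; simple fraction combinations such as
  `f(GMP-like) − f(HSC-like)` act as response classifiers evaluated by
  ROC/AUC.
* **How strongly a patient reacts epigenetically** is read from paired
  Day 0 / Day 5 5hmC profiles: the number of differentially
  hydroxymethylated genes (DhMGs; NB Wald test, raw p < 0.01 and
  |log2FC| ≥ 0.5) rises with AZA dose, and patients with stronger 5hmC
  alteration survive longer (median split, Kaplan-Meier/log-rank, Cox with
  age and sex). An XGBoost model on rlog 5hmC levels with patient-grouped
  5-fold cross-validation, split-count (F score) gene ranking and top-k
  refitting yields a compact 5hmC response signature, with shuffled-label
  controls and a hard train/test patient-leakage guard.

Because the patient-level data are access-controlled, the package ships a
synthetic-cohort generator (`sim_config()`, `generate_bulk_cohort()`,
`generate_hmc_cohort()`) that reproduces the statistical structure the
analysis assumes — NB counts as mixtures of cell-type profiles, responder
labels driven by composition, dose-dependent Day 5 shifts, survival whose
hazard falls with 5hmC alteration — with full ground truth, so every stage
is testable end to end.

## Core statistics

* Median-of-ratios size factors; TPM; `log2(count/sf + 1)` rlog
  approximation.
* NB Wald test: method-of-moments dispersion shrunk 50/50 toward an
  `a0 + a1/mean` trend, Wald statistic on a moderated Student t
  (3× residual df). DEG rule `padj ≤ 0.1 & |log2FC| ≥ 0.5`; DhMG rule
  `p < 0.01 & |log2FC| ≥ 0.5`.
* Deconvolution: fold-over-max marker selection, non-negative least
  squares in TPM space, compartment renormalization, BM/PB averaging.
* Preranked GSEA (weighted KS running sum, gene-label permutation null,
  NES, sign-matched p), per-sample rank scores, weighted signature scores.
* Co-expression modules: Pearson correlations of DEGs, average-linkage
  clustering of correlation profiles, interaction-edge extension with a
  strict 3-TPM floor.
* Survival: product-limit KM, log-rank (O−E with hypergeometric variance),
  Cox partial likelihood (Breslow ties) via the `survival` package.

See `vignettes/hmcresponse-methods.Rmd` for assumptions, parameter
defaults and design choices.

## Worked example

```r
library(hmcresponse)

cfg  <- sim_config(n_patients = 20, seed = 42)
ref  <- generate_reference_profiles(cfg)
bulk <- generate_bulk_cohort(cfg, ref)

rr <- responder_rate(bulk$sheet)
# responders 9/20 (45%)

tpm <- tpm_normalize(bulk$counts, bulk$gene_lengths_kb)
est <- estimate_fractions(tpm, build_signature(ref, 50))
pat <- average_tissues(compartment_normalize(est), bulk$sheet)
score  <- composition_score(pat, "gmp_minus_hsc")
labels <- is_responder(bulk$sheet$response[match(rownames(pat),
                                                 bulk$sheet$patient_id)])
roc_auc(score, labels)
# ROC: AUC = 0.808 (9 positives, 11 negatives)

hmc  <- generate_hmc_cohort(cfg)
pats <- unique(hmc$sheet$patient_id)
dhmg <- vapply(pats, function(p)
  as.integer(patient_dhmg_count(hmc$counts, hmc$sheet, p)), integer(1))
tapply(dhmg, hmc$truth$dose, median)
# 37.5   50   75
#   52  112  206

grp <- median_split(dhmg)
os  <- hmc$sheet[match(pats, hmc$sheet$patient_id), ]
logrank_test(os$os_time, os$os_event, grp)
# log-rank chisq = 6.74, p = 0.0094
```

Read: the malignant GMP−HSC balance separates simulated responders from
non-responders (AUC 0.81); recovered DhMG counts rise with AZA dose
(medians 52 / 112 / 206 at 37.5 / 50 / 75 mg/m²); and the high-DhMG half
of the cohort survives significantly longer (log-rank p ≈ 0.009) — the
planted structure, recovered by the full pipeline.

A thin command-line wrapper over the same functions is installed at
`inst/cli/hmcresponse.R` (subcommands `simulate`, `diff`, `deconv`,
`survive`, `run`); `run_full()` orchestrates all stages from a YAML config
and writes per-stage TSV/JSON outputs plus a provenance manifest.

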