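---
title: "Cross-cohort discovery of severe-AMS transcriptomic biomarkers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort discovery of severe-AMS transcriptomic biomarkers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amsbiomarkers)
```

# Scientific setting

Acute mountain sickness (AMS) strikes a subset of people ascending rapidly to
high altitude. Severity is scored with the cerebral factor (AMS-C) of the
shortened Environmental Symptoms Questionnaire; a score of at least 1.4
defines severe AMS (`ams_severity()`). Blood transcriptomics offers two
practical prizes: a *diagnostic* signature that separates severe (AMS+) from
non-severe (AMS−) individuals once at altitude, and — more valuable — a
*predictive* signature readable in a sea-level sample before ascent.

`amsbiomarkers` implements a complete discovery workflow for paired
sea-level (SL) / high-altitude (HA) RNA-seq studies run in two independent
cohorts: a discovery cohort whose samples train every model, and a validation
cohort used only for replication filtering and held-out evaluation. The
canonical design the package emulates has an 18-subject, fully paired
discovery cohort (36 samples, 5 severe subjects, ~28% incidence) and a
10-subject validation cohort (5 severe, ~50% incidence) whose dropouts leave
9 SL and 7 HA samples.

The workflow has five stages, each usable on its own:

1. **Synthetic data** — a negative-binomial study generator with planted,
   category-specific effects (`sim_config()`, `generate_study()`).
2. **Preprocessing** — sample QC, low-count masking with KNN imputation, TMM
   normalization, log-CPM, PCA outlier report (`preprocess_counts()`).
3. **Differential expression** — sex-adjusted negative-binomial GLMs with
   dispersion shrinkage and likelihood-ratio tests (`run_contrast()`).
4. **Biomarker taxonomy** — four contrasts with a same-direction cross-cohort
   replication filter (`common_degs()`).
5. **Panel selection** — Gini-importance ranking, forward SVM panels, and
   held-out ROC/AUC with Youden operating points (`forward_trajectory()`).

# The four-contrast biomarker taxonomy

With two timepoints and a binary severity label there are four sample groups,
and four scientifically distinct two-group contrasts (`contrast_groups()`):

| category   | comparison                   | design                      |
|------------|------------------------------|-----------------------------|
| diagnostic | AMS+ vs AMS− among HA samples | unpaired, sex-adjusted      |
| predictive | AMS+ vs AMS− among SL samples | unpaired, sex-adjusted      |
| pathogenic | SL → HA within AMS+ subjects  | paired (subject-blocked)    |
| protective | SL → HA within AMS− subjects  | paired (subject-blocked)    |

Unpaired contrasts adjust for sex as a covariate; paired contrasts include a
subject indicator per extra subject, which absorbs sex (it is constant within
subject), so no separate sex column is added. Severity is a subject-level,
time-invariant label: the AMS-C score measured at altitude labels both of a
subject's samples.

A gene is a *biomarker* for a category when it passes the DEG thresholds —
p < 0.05 **and** |log2FC| > 0.7, both strict — in **both** cohorts with the
same fold-change sign. This replication filter is the package's main guard
against single-cohort false positives; on null data it passes well under one
gene per 2000 (verified in the acceptance suite). Genes appearing in two or
more categories (e.g. both predictive and diagnostic) are flagged by
`converged_genes()`.

# Preprocessing model

The preprocessing rules mirror common practice for small-cohort blood
RNA-seq:

* **Sample filter.** A sample is removed when *strictly more than* 20% of its
  genes have raw count below 10 (`filter_samples()`). The gene set is never
  changed by this step.
* **Masking and imputation.** Counts below 10 are treated as missing
  (`mask_low_counts()`) and restored by K-nearest-neighbour imputation
  (`knn_impute()`, k = 5 by default). Sample distance is the mean squared
  difference of log2(count + 1) over mutually observed genes; the mean (not
  the sum) keeps distances comparable when attrition shortens the overlap.
  Imputation runs per cohort: cohorts are separate sequencing batches, and
  cross-cohort neighbours would leak batch signal. Genes observed in no
  sample are dropped with a warning. Imputed values are rounded to integers
  before model fitting, because the NB likelihood needs integer counts and
  the imputed fraction is small.
* **Normalization.** Trimmed-mean-of-M-values factors (`tmm_factors()`) with
  the canonical 30%/5% two-sided trims on M and A, binomial delta-method
  precision weights, a reference sample chosen by the 75th-percentile count
  fraction closest to the mean, and geometric-mean-1 rescaling. The
  implementation is validated in the test suite both against a brute-force
  trimming oracle (tolerance 1e-10) and against `edgeR::calcNormFactors()`.
* **PCA check.** `pca_outlier_check()` flags samples beyond 3 SD on PC1/PC2
  of the log-CPM matrix. It reports; it never removes.

# Differential expression model

Each gene is modelled as NB(μ, φ) with a log link,

  log μ = Xβ + offset,  Var = μ + φμ²,

where the offset is the log effective (TMM-scaled) library size and the
contrast coefficient is always the last design column. The engine is written
in the package (compiled IRLS per gene) rather than delegated to an external
DE package, for two reasons: the analysis needs a specific combination of
paired/unpaired sex-adjusted designs and shrinkage control, and re-deriving
the machinery makes every numerical choice testable. External packages are
used in the test suite only, as independent cross-checks.

**Dispersion estimation** (`estimate_dispersions()`) profiles the Cox-Reid
adjusted profile likelihood (APL = gene log-likelihood − ½ log det of the
weighted information) on a 15-point log-spaced grid over φ ∈ [1e-4, 10],
with quadratic interpolation around the grid maximum. The common dispersion
maximizes the summed APL; gene-wise estimates maximize each gene's APL; the
*shrunk* estimate used for testing maximizes

  APL_g(φ) + (prior_df / df_resid) · mean APL(φ),

which pulls small-sample estimates toward the common value. `prior_df`
defaults to 10 — deliberately strong shrinkage, appropriate when residual
degrees of freedom are scarce (e.g. 7 HA samples in the validation cohort)
and gene-wise dispersions would otherwise be underestimated, inflating false
positives. At `prior_df = Inf` every gene collapses to the common value; the
shrunk estimate is clamped to lie between the gene-wise and common
maximizers.

**Testing.** The p-value is the likelihood-ratio test of the contrast column
(χ², 1 df). log2FC is the contrast coefficient divided by ln 2, clamped at
|log2FC| ≤ 30 for separated genes (flagged). Genes with zero counts in more
than 90% of a contrast's samples are excluded; non-convergent fits get p = 1
rather than an unreliable small p. BH adjustment (`bh_adjust()`) runs within
each contrast over tested genes only. Note that DEG calling
(`call_degs()`) follows the study's thresholds on the *unadjusted* p-value;
FDR columns are reported alongside. Calibration is enforced in the
acceptance suite: on null data the type-I error at p < 0.05 must land in
[0.03, 0.07] with uniform p-values.

# Panel selection model

The diagnostic panel is trained on the discovery cohort and evaluated once on
the validation cohort — there is no cross-validation, matching the two-cohort
design.

* **Labels.** Positives are the HA samples of severe subjects
  (`label_rule = "sample"`), giving the 5-positive/31-negative training split
  of the canonical design; a subject-level rule is available. The predictive
  panel uses SL samples only, labelled by eventual severity.
* **Ranking.** `gini_rank()` grows a 10,000-tree random forest and ranks the
  pool by mean decrease in Gini impurity, with lexicographic tie-breaks so a
  fixed seed gives a reproducible ranking.
* **Panels.** `forward_trajectory()` trains a linear SVM (C = 1,
  training-cohort standardization, inverse-class-frequency weights so the
  minority AMS+ class is not ignored) on the top-k genes for k = 1..N and
  scores the held-out cohort. The best panel maximizes test AUC, smallest k
  on ties. ROC, AUC and the Youden operating point (`roc_auc()`,
  `youden_threshold()`) are computed by an in-package rank-based
  implementation, cross-checked in the tests against all-pairs counting,
  exhaustive threshold search, and `pROC`.

# The synthetic study generator

Because the package must be runnable and testable with no external data,
`generate_study()` draws a complete two-cohort study:

* counts ~ NB(μ, φ) with gene baselines log-normal (meanlog 4.5, sdlog 1.3 on
  the natural-log scale), a global φ = 0.1 (optionally gene-wise
  inverse-gamma), and per-sample log-normal library-size factors (sd 0.2);
* a log2 effect of 1.0 on 5% of genes for women, so the sex adjustment has
  something to adjust for;
* 5% of genes forced into the below-10-count regime so masking and
  imputation are exercised on every run;
* disjoint planted signal sets per category — each an (n, |log2FC|,
  fraction-up) triple — applied to the category's sample predicate:
  diagnostic effects only in (severe, HA) samples, predictive in severe
  subjects at both timepoints, pathogenic SL→HA in severe subjects,
  protective SL→HA in everyone;
* AMS-C scores with severe ~ 1.4 + |N(0.4, 0.3)| and non-severe ~ U(0, 1.3),
  so the ≥1.4 dichotomy is exact by construction;
* attrition entries (subject, timepoint) that are simply never emitted.

Default effect magnitudes are anchored to the fold-change range printed for
replicated AMS biomarkers (roughly 0.7–3.5 in log2): diagnostic 3.0
(hemoglobin-like), predictive 1.2, pathogenic 1.5, protective 1.0, half up /
half down.

**Realism and limits.** The generator reproduces the *statistical* structure
the pipeline assumes — NB counts, library-size variation, sex effects,
paired design, attrition — not biology: no gene-gene correlation, no pathway
structure, no confounding between sex and severity, and effects enter as
clean multiplicative shifts. One deliberate choice deserves emphasis:
planted signal-gene baselines are drawn from the abundance distribution
*left-truncated at a mean of 100* (`signal_min_base_mean`). The
preprocessing rules mask every count below 10 and impute it from unshifted
neighbours, so a down-shift planted on a gene whose counts sit near the
floor is erased before the model ever sees it — unidentifiable by
construction, for any method honoring these rules. Real replicated AMS
biomarkers are well-quantified transcripts (hemoglobins, HLA class II,
interferon-response genes), so the truncation also matches the phenomenon
being emulated. Recovery claims in the acceptance suite are claims about
detectable signals, and the generator makes that explicit rather than
hiding it in seed luck. Set `signal_min_base_mean = 0` to study the erasure
effect itself.

# Problem sizes and runtime

Problem sizes in examples and tests are the package's own choice: unit tests
run on 150–400 genes and 16–36 samples so the whole suite stays fast, while
the acceptance suite uses the full canonical design (2000 genes, 36 + 16
samples) and repeats recovery experiments over 25 seeds. On one CPU core a
full contrast on 2000 × 36 (dispersion grid plus final fits) takes well
under a second thanks to the compiled IRLS; a complete pipeline run
(`run_all()`) with default sizes takes a few seconds plus the 10,000-tree
forest.

# Reproducibility

Every stochastic step takes an explicit seed and restores the caller's RNG
state (`generate_study()`, `gini_rank()`), so a `run_all()` manifest plus its
seed reproduces every output byte-for-byte; the manifest records parameters,
stage summaries and MD5 hashes of all artifacts.

# Limitations

* The NB engine approximates (not replicates) mainstream DE tools: agreement
  is validated distributionally — calibrated type-I error, effect recovery —
  rather than bit-wise against any particular implementation.
* DEG calling at unadjusted p < 0.05 with a fold-change floor trades strict
  error control for sensitivity at these sample sizes; the cross-cohort
  replication filter, not the per-cohort p-value, carries the specificity
  burden.
* The generator's independence assumptions make synthetic power estimates
  optimistic relative to correlated real transcriptomes.
* No pathway/enrichment analysis is included, and the panel stage offers
  only linear SVMs — a deliberate match to the validated workflow rather
  than a modelling ceiling.
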