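# amsbiomarkers

Cross-cohort discovery of blood transcriptomic biomarkers for severe acute
mountain sickness (AMS), as a tested, reusable R pipeline.

## Background

Rapid ascent to high altitude gives a substantial minority of people severe
AMS, defined by a cerebral-factor symptom score (AMS-C) of at least 1.4.
Blood RNA-seq taken at sea level (SL) and after ascent to high altitude (HA)
in two independent cohorts — a fully paired discovery cohort and a smaller
validation cohort with dropout — makes four biologically distinct two-group
contrasts possible, each defining a biomarker category:

| category   | comparison                     | use                                  |
|------------|--------------------------------|--------------------------------------|
| diagnostic | AMS+ vs AMS− among HA samples  | recognize severe AMS at altitude     |
| predictive | AMS+ vs AMS− among SL samples  | predict severe AMS before ascent     |
| pathogenic | SL → HA within AMS+ subjects   | altitude response of the susceptible |
| protective | SL → HA within AMS− subjects   | altitude response of the resistant   |

A gene becomes a candidate biomarker only when it passes the DEG thresholds
(p < 0.05 and |log2FC| > 0.7, both strict) **in both cohorts with the same
direction** — replication, not single-cohort significance, carries the
evidential weight. Replicated candidates are then ranked by random-forest
Gini importance and assembled into forward-selection linear-SVM panels whose
ROC/AUC is evaluated once on the held-out cohort, with a Youden-index
operating point.

The package implements every stage — synthetic study generation,
preprocessing (sample QC, low-count masking + KNN imputation, TMM
normalization, PCA outlier report), sex-adjusted negative-binomial
differential expression with dispersion shrinkage, the four-contrast
taxonomy with replication filtering, and panel selection — plus a one-call
pipeline (`run_all()`) and a command-line wrapper. A synthetic two-cohort
generator with planted, category-specific effects makes everything runnable
and testable without external data. See the vignette
(`vignettes/ams-biomarker-pipeline.Rmd`) for the statistical model and all
design decisions.

## Worked example

Simulate the canonical two-cohort design (18 paired subjects for discovery;
10 subjects with attrition for validation), preprocess, run the diagnostic
contrast in both cohorts, and apply the replication filter:

```r
library(amsbiomarkers)

config <- sim_config(seed = 7L)   # 2000 genes, two cohorts, planted effects
study  <- generate_study(config)

incidence_summary(study$meta)
#>      cohort n_severe n_total percent
#> 1   Chamber        5      10      50
#> 2 PikesPeak        5      18      28

de <- lapply(names(study$counts), function(co) {
  pp   <- preprocess_counts(study$counts[[co]])
  meta <- study$meta[study$meta$cohort == co, ]
  run_contrast(pp$counts, meta, "diagnostic", factors = pp$factors)
})

set <- common_degs(de[[1]], de[[2]])    # replication filter
nrow(set)
#> [1] 58
direction_counts(set)
#>   n_up n_down
#>     29     29

planted <- study$truth$gene[study$truth$category == "diagnostic"]
mean(planted %in% set$gene)             # planted-signal recovery
#> [1] 1
```

The replicated set feeds panel selection: rank by Gini importance on the
discovery cohort, then grow panels of top-k genes and score the held-out
cohort:

```r
pp <- lapply(study$counts, preprocess_counts)
tr <- panel_features(pp$PikesPeak$log_cpm,
                     study$meta[study$meta$cohort == "PikesPeak", ],
                     set$gene, "diagnostic")
te <- panel_features(pp$Chamber$log_cpm,
                     study$meta[study$meta$cohort == "Chamber", ],
                     set$gene, "diagnostic")
ranking <- gini_rank(tr$x, tr$y, n_trees = 10000, seed = 7)
traj <- forward_trajectory(ranking, tr, te)
traj[attr(traj, "best_k"), c("k", "auc", "sensitivity", "specificity")]
#>   k auc sensitivity specificity
#> 1 1   1           1           1
```

Or run everything (including all four contrasts, TSV artifacts and a JSON
manifest) in one call:

```r
run_all(list(seed = 7L), outdir = "ams_run")
```

The same pipeline runs on real data via the `input` config block (paths to
count and metadata TSVs) instead of `simulate`; a command-line wrapper with
composable subcommands is provided in `scripts/run_pipeline.R`.

## Published candidate tables

`published_candidates()` ships the per-cohort statistics (p-value, FDR,
log2FC in each cohort) of the replicated diagnostic and predictive candidate
gene lists reported for the two-cohort AMS study this package targets, as a
worked example of the replication filter on real numbers:

```r
d <- published_candidates("diagnostic")
set <- common_degs(d$pikespeak, d$chamber)
nrow(set)
#> [1] 11
head(set$gene)
#> [1] "ISG15"        "HLA-DQB1"     "LOC101927999" "HBA2"         "HBA1"
#> [6] "FOLR3"
```

## Testing

The testthat suite validates every module against independent oracles:
brute-force double-trimming for TMM (tolerance 1e-10) plus
`edgeR::calcNormFactors()`, hand step-up for BH, all-pairs counting for AUC
(plus `pROC`), exhaustive threshold search for Youden, hand-computed
neighbour averages for KNN imputation, Poisson GLM likelihood-ratio tests
for the NB engine at φ = 0, and brute-force objective minimization for the
linear SVM.

```r
testthat::test_dir("tests/testthat", package = "amsbiomarkers",
                   load_package = "installed")
```

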