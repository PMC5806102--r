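# gpsig — rank-based gene-pair signatures for survival prognosis

`gpsig` builds prognostic signatures for survival cohorts from
**within-sample gene-pair orderings** instead of absolute expression
levels.  For an ordered pair of genes $(a, b)$ and sample $s$ the feature
is the binary indicator

$$I_{ab}(s) = \mathbf{1}\{x_{a,s} > x_{b,s}\},$$

and the risk score is a sparse linear combination
$\eta_s = \sum_k \beta_k I_{a_k b_k}(s)$ selected by L1-penalised Cox
regression (10-fold cross-validation, 1-SE rule).  Because every feature
depends only on which of two genes is higher *within* a sample, the score
and any frozen cutoff on it are exactly invariant to strictly monotone
per-sample transformations — scanner scaling, monotone normalisation,
batch shifts — so a signature trained on one microarray cohort can be
applied verbatim to another, with no batch correction.

The package is aimed at researchers developing or validating
transcriptomic prognostic signatures from expression + follow-up cohorts
(e.g. GEO series with overall-survival annotation).  It covers the whole
workflow:

* probe→gene collapse by maximal inter-quartile range, expression and
  variability pre-filters (`collapse_probes`, `filter_genes`);
* per-gene median-split log-rank screening with permutation p-values
  (`screen_prognostic_genes`, `logrank_test`, `permutation_pvalue`);
* pair enumeration and binary indicator matrices (`enumerate_pairs`,
  `build_pair_matrix`, `prune_degenerate_pairs`);
* penalised Cox selection and risk scores (`fit_penalized_cox`,
  `risk_score`), with leave-one-pair-out sensitivity and a random
  pseudo-signature control;
* time-dependent ROC at a horizon by nearest-neighbour estimation,
  corner-distance cutoff, Kaplan–Meier / hazard-ratio /
  concordance-index evaluation and subgroup analysis (`td_roc_nne`,
  `optimal_cutoff`, `group_hr`, `harrell_cindex`, `compare_cindex`,
  `subgroup_analysis`);
* a seeded synthetic-cohort generator with *planted* prognostic pairs
  (`generate_cohort`, `apply_batch_transform`, `generate_probe_matrix`),
  so every stage is testable without downloads;
* end-to-end orchestration (`run_training`, `run_validation`) and a
  shipped, frozen seven-pair gastric-cancer signature with its published
  cutoff of −0.154 (`gastric_signature`).

See the methods vignette (`vignettes/gene-pair-signatures.Rmd`) for the
model, estimator details, numerical conventions and limitations.

## Worked example

Train on a synthetic 300-sample cohort with five planted pairs
(log-hazard 0.8 each) among 50 genes, then validate on a monotonically
distorted copy of the same cohort:

```r
library(gpsig)

cfg <- synthetic_config(
  n_samples = 300, n_genes = 50,
  planted_pairs = data.frame(gene_a = c(1, 3, 5, 7, 9),
                             gene_b = c(2, 4, 6, 8, 10), beta = 0.8),
  seed = 5)
cohort <- generate_cohort(cfg)

report <- run_training(cohort$expression, cohort$survival,
                       pipeline_params(B = 300, seed = 9))
report$signature
#> Gene-pair signature: 3 pairs, 4 distinct genes
#>   cutoff: 0.033866 (score >= cutoff -> high risk)
#>   horizon: 60
#>  gene_a gene_b coefficient
#>    g008   g005 -0.06716218
#>    g008   g009 -0.45736397
#>    g005   g002  0.10102817
report$comparison
#> high vs low risk: HR 2.578 (95% CI 1.923-3.456), log-rank p 5.94e-11
#>   n_high: 162  n_low: 138
round(report$cindex$cindex, 3)
#> [1] 0.628
round(report$roc$auc, 3)
#> [1] 0.692
```

The trained signature finds pairs among the planted genes (g002…g009;
orientation is absorbed by coefficient signs), splits the cohort into a
high-risk group with 2.6-fold hazard, and concentrates real prognostic
information (C-index 0.63, 5-year AUC 0.69 against a theoretical ceiling
set by the planted effect sizes).  Applying the frozen signature to a
batch-distorted copy of the cohort reproduces every score bit-for-bit:

```r
distorted <- apply_batch_transform(cohort, shift = -4, scale = 2.5,
                                   distortion = "sigmoid")
val <- run_validation(report$signature, distorted$expression,
                      distorted$survival)
identical(val$scores, report$scores)
#> [1] TRUE
```

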