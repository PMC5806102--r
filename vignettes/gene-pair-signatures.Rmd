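---
title: "Rank-based gene-pair signatures for survival prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair signatures for survival prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsig)
```

## The model

Expression-based prognostic signatures usually combine absolute expression
levels in a Cox model.  That makes them fragile across datasets: microarray
cohorts differ by scanner scaling, normalisation pipeline and batch, so a
risk formula trained on one cohort rarely transfers to another without
re-calibration.  `gpsig` implements the alternative of building the
signature from *within-sample orderings*.  For an ordered gene pair
$(a, b)$ and sample $s$, the feature is the indicator

$$ I_{ab}(s) = \mathbf{1}\{x_{a,s} > x_{b,s} \}, $$

with exact ties scoring 0 (the "otherwise" branch of a strict comparison).
Any strictly increasing per-sample transformation of the expression vector
— affine rescaling, log/exponential warps, monotone normalisation — leaves
every $I_{ab}$ unchanged, so a risk score

$$ \eta_s = \sum_k \beta_k \, I_{a_k b_k}(s) $$

and any cutoff on it can be frozen on a training cohort and applied to a
new cohort verbatim, with no batch correction.  This invariance is the
central methodological claim, and the package asserts it *bit-exactly* in
its test suite rather than approximately.

The workflow is:

1. **Probe collapse** (`collapse_probes`): when several probes map to one
   gene symbol, keep the probe with the largest inter-quartile range —
   more robust than averaging, and deterministic (ties break to the
   smallest probe id).
2. **Pre-filters** (`filter_genes`): rank genes by mean intensity and drop
   the lowest 20% ("un-expressed"), then rank the survivors by standard
   deviation and drop the lowest 20% ("un-informative").  The two filters
   are applied sequentially; we read the filtering rule as one ranking
   criterion per filter, the only interpretation that gives a well-defined
   per-gene order.  `floor()` is used at each step, the fractions are
   configurable, and the filters are monotone in their fractions.
3. **Screening** (`screen_prognostic_genes`): each gene is dichotomised at
   its median (values at or above the median are the "high" group — a
   deterministic boundary convention) and tested with the two-group
   log-rank statistic; significance is assessed by label permutation,
   $p = (1 + \#\{S_\pi \ge S_{obs}\})/(B+1)$.  How expression should enter
   the log-rank test is genuinely open; the median split is the standard
   choice.  No multiple-testing correction is applied — the screening
   threshold `alpha` is a tunable, and the permutation count `B`
   (default 1000) bounds the attainable p-value at $1/(B+1)$.
4. **Pair construction** (`enumerate_pairs`, `build_pair_matrix`): all
   $G(G-1)/2$ unordered pairs of the screened genes, oriented by input
   order (the penalised model's coefficient signs absorb orientation).
   Constant pairs are pruned before fitting; they carry no information and
   only inflate the design.
5. **Selection** (`fit_penalized_cox`): L1-penalised Cox partial
   likelihood (Breslow ties, via coordinate descent) along a 100-value
   log-spaced penalty path down to 0.01 of the smallest all-zero penalty;
   the penalty is chosen by 10-fold cross-validation of the partial
   likelihood deviance with the 1-SE rule, which prefers the sparsest
   model statistically indistinguishable from the best.  Folds are
   stratified by event status and seeded, so fits are reproducible.
6. **Cutoff** (`td_roc_nne`, `optimal_cutoff`): a time-dependent ROC curve
   at the horizon (default 60, i.e. 5 years for monthly follow-up) using
   cumulative cases and dynamic controls; the cutoff is the score whose
   ROC point lies closest to the perfect corner (0% FPR, 100% TPR), ties
   breaking toward the lower threshold.  Classification uses
   `score >= cutoff` → high risk.
7. **Evaluation** (`group_hr`, `harrell_cindex`, `compare_cindex`,
   `subgroup_analysis`): Kaplan–Meier curves, the log-rank test, a
   univariate Cox hazard ratio with Wald CI, Harrell's concordance index,
   and a paired-bootstrap comparison of two concordance indices.

## The nearest-neighbour time-dependent ROC

At horizon $t$, cases are samples with an event by $t$ and controls are
survivors past $t$; under right-censoring, case/control status is not
observed for everyone, so the joint distribution of (marker, survival) is
estimated by smoothing.  Each sample's conditional survival
$S_i(t) = P(T > t \mid X = x_i)$ is the Kaplan–Meier estimate over its
marker-rank neighbourhood $\{j : |r_j - r_i| \le \mathrm{span}\cdot n\}$ —
a symmetric window holding about $2\,\mathrm{span}\,n$ samples.  Then

$$ \mathrm{TPR}(c) = \frac{P(X > c) - P(X > c, T > t)}{1 - S(t)}, \qquad
   \mathrm{FPR}(c) = \frac{P(X > c, T > t)}{S(t)}, $$

with $P(X > c, T > t) = n^{-1}\sum_{x_i > c} S_i(t)$.  Both rates are
monotone in $c$ by construction, the curve runs from $(1,1)$ to $(0,0)$,
and the AUC is the trapezoid integral.  The default span is
$0.25\,n^{-0.20}$, the conventional default of this estimator family; it
is a tunable because no single span suits every cohort size.

Two numerical properties worth knowing:

* In the $\mathrm{span} \to 0$ limit the smoother degenerates to the
  empirical indicator and, without censoring, the curve equals the exact
  ROC — a perfectly ordering marker scores AUC exactly 1.  At practical
  spans the corner is rounded by the neighbourhood mixing, so a perfect
  marker scores slightly below 1; the bias is $O(\mathrm{span}^2)$.
* The estimator is anti-symmetric: flipping the sign of the marker maps
  AUC to 1 − AUC (the rank-distance neighbourhoods are symmetric, so the
  smoothed survivals are identical).

## The synthetic cohort generator

`generate_cohort` emulates a microarray survival cohort of the shape used
to develop signatures of this kind (n = 300 training, n ≈ 200 validation,
follow-up in months): per-gene normal log-intensities with means around 8
and per-gene SDs in [0.5, 1.5]; event times exponential with hazard
proportional to $\exp(\eta)$ where $\eta$ sums the planted pair indicators
times their log-hazards $\beta$; administrative censoring uniform on
$[0, \tau]$ with $\tau$ solved numerically so the expected censored
fraction matches the target (default 0.3).  Independent censoring is
exactly the assumption of the KM/log-rank machinery downstream.

Three generator design choices matter:

* **Planted pairs share a mean.**  The two genes of a planted pair get the
  same baseline mean, so the indicator splits the cohort near 50/50 and
  actually carries its $\beta$; with very different means the indicator
  would be nearly constant and the "planted" signal vacuous.
* **The linear predictor is centred** before event times are drawn, so
  `baseline_scale` (default 60) remains the cohort's typical event-time
  scale whatever is planted, and a 5-year horizon stays inside the
  observed follow-up.  Hazards remain proportional to $\exp(\eta)$.
* **Probe 1 is noise-free.**  `generate_probe_matrix` gives probe $j$ of a
  gene the gene's values plus $N(0, ((j-1)\cdot\text{noise\_step})^2)$
  noise, so a single-probe expansion collapses back to the original matrix
  exactly, and the highest-index probe is the maximal-IQR representative
  with overwhelming probability.

What the generator does **not** emulate: heavy-tailed intensity
distributions, probe cross-hybridisation, spatial artifacts, correlated
gene modules, or informative censoring.  Tests passing on these cohorts
demonstrate the machinery's correctness and calibration, not clinical
performance on real arrays.

## Calibration and recovery behaviour

With nothing planted, the permutation screen rejects a fraction close to
`alpha` of genes (the suite checks 500 null genes at $B = 200$,
$\alpha = 0.05$, tolerance ±0.02).  The random pseudo-signature control —
sample 14 screened genes, pair them into 7 pairs, fit the 7 coefficients
by unpenalised Cox, evaluate the 5-year AUC — sits near 0.5 on null
cohorts, though slightly above it (≈0.55–0.60 in our runs) because the
coefficients are fitted and evaluated on the same samples; that in-sample
optimism is intrinsic to the control as published and is worth remembering
when reading its value on real data.

With 5 pairs planted at $\beta = 0.8$ among 50 genes and $n = 300$, the
1-SE LASSO selection recovers at least 4 of the 5 planted pairs in well
over 80% of seeded replicates.  The failure mode, when it occurs, is the
LASSO substituting a pair that shares a gene with a planted pair — such
indicators are correlated with the planted one, and an L1 path keeps
whichever enters first.

## Numerical conventions and degenerate inputs

* Ties: pair indicators use strict `>` (ties → 0); classification uses
  `>= cutoff` → high; samples at the gene median go to the high group;
  IQR ties in probe collapse go to the smallest probe id; cutoff ties go
  to the lower threshold.  Every tie rule is chosen for determinism.
* Cox ties use the Breslow approximation throughout (both the penalised
  path and the univariate hazard ratios), matching the conventional
  penalised-path implementation.
* Signature files serialise coefficients at 17 significant digits, which
  round-trips IEEE doubles losslessly.
* Degenerate inputs error early and by name: zero-sample/zero-gene
  configs, non-positive follow-up times, single-group log-rank calls,
  event-free cohorts, constant designs, signatures referencing genes
  absent from the validation cohort.
* Cohorts whose median split is degenerate (constant genes) are skipped in
  screening with a logged count; strata with fewer than two events are
  flagged and skipped in subgroup analysis, never fabricated.

## Problem sizes in the test suite

The suite exercises the study-shaped conditions directly: cohorts of
n = 300 with 50 genes (1225 candidate pairs) for selection and batch
invariance, 500 null genes at B = 200 permutations for screening
calibration, 20 seeded replicates for recovery, and n ≤ 50 fixtures for
the brute-force oracle comparisons.  These sizes were chosen as the
smallest at which each property is a meaningful statistical statement.

## Known limitations

* Refitting on a new cohort is not expected to reproduce any particular
  published coefficient table: penalty-path selection under
  cross-validation is stochastic in its fold assignment, and the chosen
  penalty of published signatures is generally unreported.  The shipped
  seven-pair gastric-cancer signature is therefore a frozen fixture for
  scoring and validation, not a refitting target.
* The concordance comparison uses a paired bootstrap rather than a
  closed-form dependent-C variance; it is transparent and testable, at
  the cost of compute.
* The screening stage tests each gene marginally; pairs whose genes have
  no marginal effect but a strong joint ordering effect can be missed
  before pair construction.  This mirrors the screening-then-pairing
  design of the original workflow.
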