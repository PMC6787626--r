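---
title: "Methods: weighted standing time severity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted standing time severity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wstsev)
```

## The problem and the model

Myalgic encephalomyelitis / chronic fatigue syndrome (ME/CFS) lacks a
quantitative diagnostic marker; routine pathology results of patients are
mostly unremarkable. One reproducible functional deficit is orthostatic
intolerance, measured by a 20-minute standing test with heart-rate and
blood-pressure recordings at 2-minute intervals. `wstsev` analyses cohorts
assessed with that protocol.

The central statistic is the **weighted standing time**

$$\mathrm{WST} = t \left(1 - \frac{d}{14}\right),$$

where $t \in \{0, 2, \dots, 20\}$ is the standing time in minutes and $d$
the standing-difficulty code: the self-reported ordinal 0–10 scale for
participants who stood the full 20 minutes, 12 for those who stood at least
10 but under 20 minutes, and 14 for those unable to stand 10 minutes (so a
code-14 participant always scores 0 weighted minutes or, for short partial
stands, close to it). WST runs from 0 (worst) to 20 × 13/14 ≈ 18.57
(a full stand at difficulty 1).

Severity classes are defined from diagnosis and the standing test:

| class | definition | WST range |
|---|---|---|
| 0 | healthy control | 14.29–18.57 |
| 1 | mild: ME/CFS, 20 min at difficulty 0–3 | 15.71–18.57 |
| 2 | moderate: ME/CFS, 20 min at difficulty 4–10 | 5.71–14.29 |
| 3 | severe: ME/CFS, < 20 min standing (codes 12/14) | 0.00–2.57 |

Two documented edge cases. First, difficulty 4 belongs to the healthy
definition (1–4) *and* the moderate definition (4–10); diagnosis is primary,
so a control at difficulty 4 is class 0 and an ME/CFS case at difficulty 4
is class 2. Second, published tables print 6.43 as the class-2 lower bound,
which is not derivable from "20 min at difficulty 4–10" (that gives 5.71);
it is evidently the observed cohort minimum. `wst_class_ranges()`
reproduces the theoretical ranges, and the class 0/1/3 boundaries match the
printed ones exactly.

For machine learning, classes 0 and 1 are pooled (`merge_classes()`): class
imbalance (17 controls) otherwise prevents a usable model, and all model
results are reported on the merged 3-class scale. POTS is flagged as a
heart-rate rise of ≥ 30 bpm on standing; it is carried as a covariate, not
used in class definitions.

## Parameters that matter

* **Random forest** (`rf_params()`): `mtry = 4` predictors tried per node,
  `ntree = 5000` trees, bootstrap with replacement. These are the published
  settings for this cohort size (~100 cases, 6 features); `ntree` buys
  stability of out-of-bag (OOB) estimates, not accuracy. Tests and examples
  scale `ntree` down (200–1000) purely for runtime; this is stated wherever
  it is done.
* **Decision tree** (`tree_params()`): `minsplit = 20`, complexity
  parameter `cp` in 0.01–0.085 (0.14 for the two-cohort comparison). Here
  `cp` gates splits on the root-scaled relative Gini-impurity improvement —
  a pre-pruning analogue of classical cost-complexity pruning. The
  behavioural contract is the same at the extremes (`cp = 0.99` gives a
  root-only tree; a cleanly separable feature yields the single obvious
  split), but threshold-for-threshold parity with other CART
  implementations is not claimed.
* **Significance level** `alpha = 0.05` throughout, with *no*
  multiple-testing correction — a faithful-reproduction choice mirroring
  the source analysis, not a statistical endorsement. The dual criterion in
  `marker_test_battery()` (flag a marker only when Kruskal–Wallis *and*
  Jonckheere–Terpstra are both significant) is the package's robustness
  screen.
* **Feature panel** (`default_feature_panel()`): MCH (pg), lymphocytes
  (×10⁹/L), serum urea (mmol/L), ALP (U/L), 24-h urinary creatinine
  excretion (mmol/24 h), activin B (pg/mL).
* **Missingness**: 24-h urine markers are missing for participants who did
  not return the urine collection; the generator injects 17.5% (the middle
  of the reported 15–20% band) and `impute_class_median()` fills gaps with
  the median of the row's own 4-class severity group. Imputation happens on
  the 4-class labels because data cleaning precedes class merging in the
  workflow; this is configurable.

## What the synthetic generator emulates — and what it does not

No raw participant data is deposited, so the package carries a seeded
generator (`generate_cohort()`) whose defaults are the published cohort:
class sizes 17/19/38/23 (97 participants, 36 in the merged class 0),
per-class marker distributions parameterised by the published medians and
25th–75th IQRs, uniformly drawn class-consistent (time, difficulty) pairs,
and 17.5% missingness in urinary creatinine.

Markers are simulated as **log-normal** marginals: they are positive and
mostly right-skewed, and the published normality screen rejects a normal
fit for most of them. `fit_lognormal_from_quantiles()` matches the median
exactly and the quartile *ratio* q75/q25 exactly; the individual quartiles
are matched only when the printed triple is log-symmetric. Two printed
sodium summaries place the median outside its own IQR (presumed
typographical errors); the default spec table stores those triples
re-sorted.

Deliberate non-features, which bound what a green test establishes:

* Markers are drawn **independently within class**; no within-class
  correlation structure is published, so none is invented. Analyses that
  exploit marker correlations (e.g. multivariate margins of the forest)
  are therefore *not* validated by the synthetic cohort.
* POTS prevalence is not published; the generator defaults to 0 for
  controls and 0.30 for ME/CFS classes, in line with POTS comorbidity
  rates reported for comparable ME/CFS cohorts. It is a configuration
  parameter, not an estimate.
* Age, DASS-42 total and Epworth scores are simulated like any other
  positive marker; no questionnaire substructure is modelled.
* No longitudinal trajectories and no assay-noise model for activin B.

Because the cohort-specific published numbers (OOB error 38.14%, AUCs
0.755/0.795/0.704/0.963, tree thresholds 11.96 mmol/L and 62.5 U/L) derive
from the undeposited data, the test suite checks *properties* instead:
exact WST boundary arithmetic, generator parameter recovery, the
AUC–Mann-Whitney identity, exact-vs-approximate agreement of the trend
test, type-I error calibration, forest separability/chance behaviour, and
the correct-prediction restriction never lowering pairwise AUC on
separable data (the qualitative 0.755 → 0.963 pattern).

## Numerical choices

* **Quantiles**: linear interpolation between order statistics (R type 7)
  everywhere — descriptives, reference intervals, generator fitting.
* **Mann–Whitney U**: midrank tie handling;
  exact two-sided p (via the exact null distribution) when
  `n1 * n2 <= 400` and untied, otherwise a tie-corrected normal
  approximation without continuity correction, which makes the two-group
  Kruskal–Wallis p identical to the Mann–Whitney p by construction.
* **Jonckheere–Terpstra**: ties count ½ in $J$. For total $n \le 12$ the
  p-value is exact — computed as a convolution of Mann–Whitney null
  distributions for untied data (a classical factorisation of the
  permutation null), by full enumeration when ties are present. Otherwise
  a normal approximation with the tie-corrected (Hollander–Wolfe) variance
  and a 0.5 continuity correction is used: measured over all untied
  fixtures with $n \le 12$, the correction brings the worst
  exact-vs-approximate gap from 0.09 to 0.014 when every group has ≥ 3
  members. For 2-member groups the discrete null is too coarse for *any*
  normal approximation (worst gap ~0.09 even with the correction) — exact
  mode covers those. Default alternative is two-sided (twice the smaller
  tail, capped at 1); the direction of the severity trend is not asserted.
* **Forest**: fully grown Gini CART trees; per-node feature subsampling;
  OOB vote ties break toward the lowest class index, so results are
  reproducible at a fixed seed. Gini importance is the node-weighted
  impurity decrease summed per feature and averaged over trees;
  permutation importance is the mean per-tree decrease in OOB accuracy
  when the feature is shuffled among that tree's OOB cases.
* **ROC**: thresholds swept over unique scores; tied scores move the curve
  diagonally in one step; AUC is trapezoidal and equals the Mann–Whitney
  pair-count probability to machine precision (tested at 1e-12). Pairwise
  class ROC scores each case by its OOB vote fraction for the
  *higher-severity* class of the pair, so AUC reads as "discriminates the
  more severe class from the less severe".
* **Reference intervals**: the (q25, q75) band with its median — *not* the
  clinical 2.5–97.5% convention. Overlap uses closed intervals (touching
  endpoints overlap) and reports a signed width: positive overlap length
  or negative gap.

## Design choices where the design was open

* "Correctly predicted" means *OOB-correct*: the source analysis reports
  OOB error rates and never mentions a held-out split, so the
  correct-prediction subset, the restricted ROC curves and the restricted
  reference intervals all condition on OOB agreement.
* The ensemble comparison (`compare_ensembles()`) runs in-package
  stand-ins — the forest, AdaBoost.SAMME over shallow CART trees,
  one-vs-rest logistic boosting on regression stumps, and a linear
  one-vs-one Pegasos SVM — because no external boosting/SVM implementation
  is assumed at run time. Algorithm parity with any specific gbm/c5.0/SVM
  configuration is explicitly not attempted; the comparison's contract is
  behavioural (all methods excel on separable data, all collapse to chance
  on permuted labels).
* The pipeline derives per-stage seeds from one global seed by a stable
  hash of the stage name, so any stage can be re-run in isolation with the
  stream it had inside `run_pipeline()`.
* Class-balancing scripts are deliberately not implemented; the merged
  3-class design is the supported remedy for class imbalance.

## Known limitations

* At weak class signal the OOB error of even a 5000-tree forest moves by
  several percentage points across forest seeds (measured: 4.1 pp range
  over 5 seeds on the default synthetic cohort, where ~a third of cases
  sit near 50/50 OOB vote margins and one case is ~1 pp). Seed-stability
  to < 2 pp holds on well-separated data; on weak-signal data, OOB error
  should be read with that uncertainty in mind.
* The generator's independence assumption makes multivariate structure in
  real cohorts invisible to the tests (see above).
* The Kolmogorov–Smirnov screen estimates the normal parameters from the
  sample and applies no small-sample correction, which is conservative;
  it is used only to justify rank-based tests, matching routine practice.
* Exact Jonckheere–Terpstra mode is limited to total n ≤ 12 (the
  enumeration path grows multinomially); beyond that the corrected normal
  approximation is used regardless of tie structure.
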