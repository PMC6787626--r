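# wstsev

Severity scoring and biomarker analysis for myalgic encephalomyelitis /
chronic fatigue syndrome (ME/CFS) cohorts assessed by a 20-minute
orthostatic-intolerance standing test.

ME/CFS has no quantitative diagnostic marker, and routine pathology results
are mostly unremarkable. This package implements an analysis workflow built
around the **weighted standing time (WST)**, a severity proxy that
down-weights the time a participant stayed upright by their subjective
standing difficulty:

```
WST = t × (1 − d/14),   t ∈ {0, 2, …, 20} min,   d ∈ {0…10, 12, 14}
```

where difficulty is self-reported (0–10) for participants who completed the
20 minutes, coded 12 for a 10–18-minute stand and 14 for an inability to
stand 10 minutes. WST stratifies a cohort into severity classes — healthy
(0), mild (1), moderate (2), severe (3), with 0+1 merged for machine
learning — and the package then runs, per marker panel:

* class-median imputation of missing 24-h urine markers;
* a nonparametric battery: Kolmogorov–Smirnov normality screen,
  Mann–Whitney U, Kruskal–Wallis, and a Jonckheere–Terpstra trend test with
  exact (total n ≤ 12) and tie-corrected normal p-values, plus a dual
  KW + J-T "robust marker" criterion;
* a seeded random-forest severity model (mtry = 4, ntree = 5000, bootstrap
  with replacement) with out-of-bag (OOB) confusion, error rates, and both
  Gini and permutation importance rankings — implemented in-package,
  including the CART grower used for marker-threshold decision trees;
* pairwise severity-class ROC/AUC from OOB vote fractions, for all cases
  and restricted to correctly predicted cases;
* median/(25th–75th IQR) reference intervals per marker per class, with
  between-class overlap assessment, optionally on correctly predicted
  cases only.

The original participant data is not publicly deposited, so the package
ships a seeded synthetic cohort generator (`generate_cohort()`) whose
defaults reproduce the published cohort structure: class sizes 17/19/38/23
(97 participants), per-class log-normal marker distributions matched to the
published medians and IQRs, and 15–20% missingness in 24-h urine markers.
See the methods vignette (`vignettes/wst-severity-methods.Rmd`) for what
the generator does and does not emulate.

## Worked example

```r
library(wstsev)

cohort <- generate_cohort(cohort_config(seed = 42))   # 97 synthetic participants
cohort <- score_standing_tests(cohort)                # adds wst, class4, class3, pots
cohort <- impute_class_median(cohort)                 # urine markers, own-class median
table(class4 = cohort$class4)
#> class4
#>  0  1  2  3
#> 17 19 38 23

model <- fit_rf(cohort[, default_feature_panel()], cohort$class3,
                rf_params(ntree = 1000, seed = 1))
model
#> Random-forest severity model: 1000 trees, mtry = 4
#> OOB error: 46.39% overall (n = 97)
#>     predicted
#> true  0  1  2
#>    0 17 13  6
#>    1  9 25  4
#>    2  8  5 10
#> Permutation importance ranking: urinary_creatinine > urea > mch > alp > lymphocytes > activin_b
#> Gini importance ranking:        urinary_creatinine > urea > mch > lymphocytes > alp > activin_b

pairwise_class_roc(model, cohort, c("0", "1"))
#> ROC (class 0 vs 1)
#> AUC = 0.719 (n_pos = 38, n_neg = 36)
pairwise_class_roc(model, cohort, c("0", "1"), correct_only = TRUE)
#> ROC (class 0 vs 1) [correctly predicted cases only]
#> AUC = 0.976 (n_pos = 25, n_neg = 17)

class_reference_intervals(cohort, "urinary_creatinine", "class3")
#>               marker group  n median  q25  q75 correct_only
#> 1 urinary_creatinine     0 36  10.36 9.62 12.9        FALSE
#> 2 urinary_creatinine     1 38   9.74 7.78 11.1        FALSE
#> 3 urinary_creatinine     2 23  10.19 9.83 10.8        FALSE
```

Reading the numbers: on a weak-signal synthetic cohort the forest's OOB
error is high (46%), but restricting the class 0-vs-1 ROC to
correctly OOB-predicted cases lifts the AUC from 0.72 to 0.98 — the same
qualitative improvement the method is designed to expose on clinical data,
where the 24-h urinary creatinine excretion rate also ranks first among
the panel markers. `run_pipeline(pipeline_config(...))` executes all of the
above plus the decision tree, the full ROC grid and the interval-overlap
report, and writes TSV/JSON artefacts with a markdown summary.

There is also a CLI covering each stage
(`synth`, `score`, `impute`, `test`, `model`, `roc`, `ri`, `run`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "wstsev.R", package = "wstsev"))')" \
    synth --seed 1 --out cohort.csv
```

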