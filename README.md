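# ddnselect

Hybrid two-stage feature selection for predicting binary behavioral
outcomes from small, mixed-type clinical cohorts — the regime of ~100
patient records, 50+ continuous/binary/categorical predictors, minority
outcomes and missing values, where filter selectors keep redundant
features, wrappers overfit, and penalized linear models miss nonlinear
effects.

**Who it is for.** Biostatisticians and clinical ML practitioners who
need a small, reproducible feature-selection pipeline for tabular cohort
data (the motivating application is long-term behavioral outcomes in
young leukemia survivors), plus a seeded synthetic-cohort generator for
validating every stage without access to protected health data.

## The method

**Stage 1 — multimetric majority-voting filter.** Each candidate feature
X is scored against the outcome Y by four relevance metrics: the maximal
information coefficient MIC(X, Y), the Gini-impurity relevance 1 − GI,
the information gain IG = H(Y) − H(Y|X) in bits, and a type-aware
absolute correlation CS (Pearson / point-biserial / φ). The top N
features per metric are collected (N = 15 by default); features selected
by ≥ 3 metrics form the high-confidence set F_3M+, features selected by
exactly 2 form the candidate set F_2M. Redundant pairs — both
1 − MIC(Xi, Xj) < 0.05 and 1 − CS(Xi, Xj) < 0.05 — are pruned, dropping
the member with fewer votes, then the worse average rank.

**Stage 2 — deep dropout network wrapper.** If |F_3M+| < N, every subset
Z ⊆ F_2M with |Z| ≤ N − |F_3M+| is appended to F_3M+ and scored by mean
stratified 5-fold CV F1 of a 2-hidden-layer ReLU network with dropout
(width ⌈(I+1)/2⌉, sigmoid output, Adam at 0.001, binary cross-entropy),
with the dropout rate grid-searched once on the baseline set. The final
list is the best candidate if it strictly beats the baseline F1, else
F_3M+ alone.

Around the selector: group-wise mean/mode imputation, one-hot encoding,
normality-guided normalization (2-of-3 vote of Shapiro–Wilk, KS and
D'Agostino–Pearson deciding z-score vs min-max), SMOTE-NC balancing,
stratified splitting, downstream evaluation with logistic regression /
naive Bayes / kNN, baseline selectors from the four classical families,
unified metric values and radial feature charts.

## Worked example

```r
library(ddnselect)

co  <- generate_cohort(cohort_spec(seed = 7))   # 102 x 50 mixed cohort,
                                                # 5 planted effects
cfg <- run_config(outcomes = "outcome", seed = 7, out_dir = "runs",
                  ddn = ddn_config(epochs = 150,
                                   dropout_grid = c(0, 0.1, 0.3, 0.5),
                                   seed = 7))
res <- run_pipeline(cfg, table = co$table, schema = co$schema)
r <- res$outcome
print(r$stage1); print(r$selection); print(r$report)
intersect(co$truth$planted$name, r$final_features)
```

prints

```
<stage1_result>
 selected by >=3 metrics: 10 feature(s)
 selected by exactly 2:   7 feature(s)
 redundancy removals:     0
<selection_result> 10 final feature(s); baseline F1 0.884, best dropout 0.00, 119 subset(s) searched
<evaluation_report> outcome: outcome
          classifier precision    recall        f1
 logistic regression 0.7777778 0.9130435 0.8400000
         naive Bayes 0.6800000 0.7391304 0.7083333
 k-nearest neighbors 0.6774194 0.9130435 0.7777778
mean F1 0.775 (variance 0.0043) over 3 classifiers
[1] "rel_lin_a"  "rel_lin_b"  "rel_lin_c"  "rel_thresh"
```

Stage 1 kept 10 high-confidence and 7 candidate features, stage 2
searched the 119 admissible candidate subsets and found none that beat
the baseline CV F1 of 0.884, so the 3-metric features were kept; 4 of
the 5 planted predictors (all but the weak interaction effect) were
recovered, and the final list scores a mean test F1 of 0.775 across the
three downstream classifiers. Each run writes `stage1.json`,
`selection.json`, `subset_log.csv`, `report.csv`, a radial chart SVG and
a `manifest.json` per outcome under `out_dir`.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/select simulate --out data --seed 1
Rscript inst/cli/select run --data data/cohort.csv --schema data/schema.yaml \
        --outcome outcome --n 15 --seed 7 --out runs
```

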