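# gfrens

Glomerular filtration rate (GFR) estimation from serum creatinine, age
and sex — a four-branch piecewise power-law estimating equation, learned
member models (a small neural network and a support vector regression)
combined by **ensemble averaging**, and the complete validation framework
used to compare GFR equations: bias, precision and P30 accuracy with
percentile-bootstrap confidence intervals, paired significance tests
against a benchmark, and GFR-stratified subgroup reports. A seeded
synthetic CKD cohort simulator makes the whole pipeline runnable and
auditable without patient data.

Intended users: nephrology methods researchers and biostatisticians who
develop or externally validate GFR estimating models.

## The models

The estimating equation is piecewise in sex and a sex-specific
creatinine threshold τ (1.2 mg/dl female, 1.0 mg/dl male):

```
eGFR = k × (SC / τ)^c × a^Age      (ml/min/1.73 m²)

female, SC ≤ 1.2 :  92 × (SC/1.2)^-0.534 × 0.994^Age
female, SC > 1.2 :  79 × (SC/1.2)^-0.516 × 0.994^Age
male,   SC ≤ 1.0 :  98 × (SC/1.0)^-0.450 × 0.996^Age
male,   SC > 1.0 : 105 × (SC/1.0)^-0.640 × 0.993^Age
```

The learned members use the same covariates (age, male indicator,
ln SC) standardized with development-set statistics; the **ensemble** is
the element-wise arithmetic mean of the regression, ANN and SVM
predictions. Averaging approximately unbiased members whose errors point
in different directions shrinks the spread of the combined error — the
ensemble is built for precision, not for bias.

Validation metrics, per model and per measured-GFR stratum
(Overall, <30, 30–60, ≥60 by default): bias = median(mGFR − eGFR),
precision = IQR of the differences, accuracy = proportion within ±30% of
mGFR, all with 2000-resample percentile-bootstrap 95% CIs; candidates
are tested against the benchmark with the Wilcoxon signed rank test
(bias), a paired bootstrap on the IQR (precision) and McNemar's test
(accuracy).

## Worked example

```r
library(gfrens)

# one patient
estimate_gfr_regression(age = 55, sex = "female", scr = 1.8)
#> [1] 46.02726

# full pipeline on synthetic cohorts
dev <- simulate_cohort(cohort_preset("development", seed = 101))  # n = 1002
val <- simulate_cohort(cohort_preset("validation",  seed = 202))  # n = 417
ann <- train_member("ann", dev, seed = 7)
svm <- train_member("svm", dev, seed = 7)
reg <- regression_member()
preds <- list(regression = predict(reg, val),
              ann        = predict(ann, val),
              svm        = predict(svm, val),
              ensemble   = predict(gfr_ensemble(reg, ann, svm), val))
report <- evaluate_models(val, preds, benchmark = "regression",
                          B = 2000, seed = 7)
report
```

Excerpt of what this run prints (the precision block):

```
Precision = IQR of the difference (95% CI)
| Model | Overall | <30 | 30-60 | >=60 |
| --- | --- | --- | --- | --- |
| regression | 10.8 (8.8-12.7) | 3.7 (2.9-4.8) | 9.3 (6.5-10.9) | 20.3 (17.2-26.0) |
| ann | 8.0 (6.8-9.1) ‡ | 3.1 (2.3-4.3) | 7.6 (5.7-10.0) | 13.2 (11.1-15.7) ‡ |
| svm | 7.6 (6.8-9.2) ‡ | 4.0 (3.1-5.2) | 7.6 (5.6-8.6) | 14.8 (12.1-17.1) ‡ |
| ensemble | 7.0 (6.3-8.5) ‡ | 3.1 (2.6-4.1) | 6.9 (6.0-8.7) | 15.3 (11.9-18.7) ‡ |
```

Reading it: on this synthetic external-validation cohort the ensemble's
error IQR (7.0 ml/min/1.73 m²) is smaller than the regression
benchmark's (10.8), and the dagger marks the paired bootstrap test as
significant at p < 0.05 — the precision gain ensemble averaging is
designed to deliver. Bias and accuracy blocks, and a table of the
comparison p-values at three decimals, follow in the same report.
`write_report(report, "report.json")` serializes the report losslessly;
`render_report(report, "tsv")` gives a tab-separated rendering.

A thin command-line surface over the same functions ships in
`inst/cli/gfrens.R` with `simulate`, `train`, `estimate` and `evaluate`
subcommands.

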