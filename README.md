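# osatriage

Hybrid fuzzy–statistical decision support for obstructive sleep apnea (OSA)
triage.

Confirmatory sleep studies are scarce; a screening-stage system helps decide
which referred patients should get one. `osatriage` implements a two-engine
design for sleep-unit populations:

* **Statistical Risk** — a bagged-tree classifier (bootstrap-aggregated
  decision trees) over the objective health-record features: sex, age, BMI,
  neck circumference, smoking/drinking habits, 12 comorbidity flags and 6
  treatment flags. Features are dummy-encoded (c − 1 indicators per
  c-category variable) and min–max normalized; classes are balanced with
  SMOTE-NC (k = 5, both classes oversampled to 4000) and evaluated with
  stratified 5-fold cross-validation. The risk is 100 × P(OSA).
* **Symbolic Risk** — a three-level cascade of seven Mamdani fuzzy expert
  systems over the 13 sleep-interview answers (min implication, max
  aggregation, centroid defuzzification). Level 1 scores four symptom groups
  (R1.a sleep time, R1.b unrefreshing sleep, R2.a complicating factors, R2.b
  snoring); level 2 fuses them into R1 and R2; level 3 yields a preliminary
  0–10 risk, rescaled to 0–100.

The two risks are fused through a utility stage. Each risk maps to a level
(1 below Limit 1; 2 on [L1, L2); 3 at or above L2; defaults 45/60 for the
statistical branch, 45/65 for the symbolic branch), levels score 0/1/2
points, and

```
T = W_ST · score_ST + W_SY · score_SY,   W_ST = 2 − W_SY ∈ [0, 2]
```

with unit weights by default. `T < 2` → non-OSA (green), `2 ≤ T < 3` →
doubtful (orange), `T ≥ 3` → possible OSA (red).

Because no patient-level data are published, the package also ships a seeded
synthetic cohort generator (`generate_cohort()`) emulating a referred
sleep-unit population (n = 4400, 61.2% with AHI ≥ 15, log-linear AHI model
on anthropometrics and comorbidities, symptom answers coupled to AHI), so
the entire pipeline is trainable and testable end to end. See
`vignette("osa-triage-methods")` for the model details and design rationale.

## Worked example

```r
library(osatriage)
library(dplyr)

# a seeded synthetic sleep-unit cohort with planted effects
cohort <- generate_cohort(cohort_spec(n = 4400), seed = 42)
mean(cohort$ahi >= 15)
#> [1] 0.6070455

# Statistical-Risk engine: encode, balance (SMOTE-NC inside each CV fold),
# fit 30 bagged trees, 5-fold CV
model <- fit_osa_classifier(cohort, trees = 30, seed = 42)
glance(model) %>% select(auc, auc_prebalanced, accuracy, sensitivity, specificity)
#> # A tibble: 1 × 5
#>     auc auc_prebalanced accuracy sensitivity specificity
#>   <dbl>           <dbl>    <dbl>       <dbl>       <dbl>
#> 1 0.837           0.915    0.768       0.800       0.718

# the shipped single-patient example: 34-year-old male non-smoker, BMI 24.6,
# neck 46 cm, frequent nocturia and witnessed apneas, habitual loud snorer;
# his sleep study later measured AHI 11.90 (below the 15 events/h threshold)
patient <- case_study_patient()
assessment <- assess(patient, model)
assessment %>%
  select(statistical_risk, symbolic_risk, statistical_level, symbolic_level,
         T, recommendation, alert_color)
#>   statistical_risk symbolic_risk statistical_level symbolic_level T
#> 1         23.11111      62.49985                 1              2 1
#>   recommendation alert_color
#> 1        NON_OSA       green
```

Reading the output: the objective branch sees an unremarkable record
(risk 23, below Limit 1 → level 1, 0 points); the interview branch sees
worrying snoring/apnea symptoms (risk 62.5, between the limits → level 2,
1 point); `T = 0·1 + 1·1 = 1 < 2`, so the system recommends *not*
performing diagnostic studies — consistent with the patient's AHI of 11.9.
All cascade intermediates stay available for audit:

```r
symbolic_risk(patient) %>% select(r1a:symbolic_risk)
#>        r1a      r1b      r2a      r2b       r1       r2 preliminary symbolic_risk
#> 1 6.249997 1.250008 8.749992 7.499995 3.750015 8.749955    6.249985      62.49985
```

`autoplot()` methods exist for linguistic variables, whole Mamdani systems,
fitted classifiers (pooled CV ROC) and assessment tables; `tidy()`/`glance()`
expose per-fold and summary CV metrics. A thin command-line front end with
`simulate`, `train`, `assess`, `batch` and `validate-rules` subcommands is
installed at `inst/cli/osatriage.R`.

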