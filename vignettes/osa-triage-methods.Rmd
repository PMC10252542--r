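---
title: "Methods: hybrid fuzzy-statistical triage for obstructive sleep apnea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid fuzzy-statistical triage for obstructive sleep apnea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osatriage)
```

## The problem

Obstructive sleep apnea (OSA) is grossly under-diagnosed because confirmatory
sleep studies (polysomnography or cardiorespiratory polygraphy) are scarce and
expensive. A screening-stage decision support system can rank referred
patients by the likelihood that a sleep study will find moderate-to-severe
disease (apnea-hypopnea index, AHI, at or above 15 events/hour), so that
scarce studies go to the patients most likely to need them.

`osatriage` implements a two-engine design. The engines see *disjoint* parts
of the patient record and quantify risk with deliberately different
formalisms:

* **Statistical Risk** — a bagged-tree classifier over the *objective*
  health-record features (sex, age, BMI, neck circumference, smoking and
  drinking habits, 12 comorbidity flags, 6 treatment flags). Uncertainty is
  handled probabilistically; the risk is 100 times the ensemble's OSA class
  probability.
* **Symbolic Risk** — a three-level cascade of seven Mamdani fuzzy expert
  systems over the 13 *subjective* sleep-interview answers. Uncertainty is
  handled through fuzzy membership, and the knowledge base is a set of
  human-readable IF-AND-THEN rules.

A final utility stage maps each risk to a level via clinical thresholds,
levels to scores, and combines the scores into a decision variable `T` that
drives a three-way recommendation (non-OSA / doubtful / possible OSA) with a
green / orange / red alert.

## The Mamdani engine

Each expert system is a classical Mamdani fuzzy inference system:

1. **Fuzzification.** Every input variable is partitioned into symmetric,
   normal, convex trapezoidal terms (`trapmf`; triangles are trapezoids with
   a degenerate plateau). A crisp value receives one membership degree per
   term.
2. **Rule evaluation.** Rules are conjunctions, `IF x1 is A AND x2 is B THEN
   y is C`; the firing strength is the *minimum* of the antecedent degrees.
   OR connectives, hedges and rule weights are not supported.
3. **Implication.** Each rule's consequent term is truncated at the firing
   strength (*minimum* implication).
4. **Aggregation.** Truncated consequents are superposed with the *maximum*
   operator.
5. **Defuzzification.** The crisp output is the centroid of the aggregated
   envelope, computed on a discretised grid (1001 points per output universe
   by default). The integrator treats the sampled envelope as piecewise
   linear and integrates each grid cell exactly, which keeps the centroid of
   the shipped term shapes within `1e-6` of the closed-form value and makes
   doubling the grid change outputs by well under 0.01 on the 0-10 scale.

Inputs fractionally outside a variable's universe (within 1% of its range)
are clamped with a warning — entry forms round; anything further out is a
hard error naming the variable. An all-zero envelope ("no rule fired") is an
error rather than a silent 0, because it means the rule base does not cover
the input box; `validate_cascade()` exists to catch that before deployment.

## The cascade

Level 1 maps the four interview groups to four risk indicators: sleep-time
items to R1.a, unrefreshing-sleep items to R1.b, complicating factors
(nocturia, breathless awakenings, witnessed apneas, unjustified awakenings)
to R2.a, and snoring items to R2.b. Level 2 fuses (R1.a, R1.b) into R1 and
(R2.a, R2.b) into R2; level 3 fuses (R1, R2) into a preliminary risk on
0-10, which is rescaled by 10 to the 0-100 Symbolic Risk. All intermediate
risks are returned for audit.

Interview answers are encoded onto numeric scales before fuzzification:
frequency answers No / Occasionally / Often become 0 / 5 / 10, yes-no items
become 1 / 0, and the snorer item becomes 0 (non-snorer), 1 (supine-position
only) or 2 (habitual snorer). Hours of sleep (0-14 h) and minutes to fall
asleep (0-240 min) pass through as numbers.

### Authored defaults

The shipped configuration is an authored default, declared and overridable
(`write_cascade()` / `read_cascade()` serialise it to an auditable JSON
document):

* **Term sets.** Interview variables get 3 terms, risk variables 5 terms
  (Very_low ... Very_high) — the granularity the printed example rules of the
  source knowledge base use. Input partitions are uniform with ~50% overlap,
  so adjacent degrees sum to 1 on the ramps.
* **Output geometry.** The five output-side risk terms are *congruent*
  symmetric trapezoids centred at 0, 2.5, 5, 7.5 and 10 on an extended
  defuzzification universe `[-1.875, 11.875]`. Congruence makes the centroid
  of any equal-strength union of terms sit exactly at the mean of their
  centres; this is what makes the inferred risk surfaces monotone, and it
  lets the inferred risks reach the ends of the 0-10 scale. (A first design
  with terms clipped to `[0, 10]` was rejected: truncating an asymmetric
  shoulder term drifts its centroid inward, which produced dips of up to 0.5
  in otherwise monotone surfaces.)
* **Rule bases.** A complete conjunctive rule base is *generated* for every
  system from a monotone severity map: each input term carries a severity in
  `[0, 1]`, and the weighted mean severity of a cell selects the output
  term. Cells landing exactly halfway between two output terms emit both
  rules — an intentional bifurcation; max-aggregation resolves it to the
  midpoint. The clinically established example rules are then added
  verbatim, including the single-antecedent rules (a non-snorer's snoring
  risk is very low on its own; constantly witnessed apneas make the risk
  very high on their own) and one bifurcated sleep-time pair. Rule counts
  are reported by `validate_cascade()` rather than forced to any particular
  total: inventing hundreds of unverifiable rules to match a count would be
  false precision.
* **Severity directions and weights.** Risk decreases with hours of sleep
  (short sleep is the severe end) and increases with every other item.
  Prolonged awakenings weigh double in the sleep-time system; witnessed
  apneas weigh 3 and nocturnal symptoms 1.5 in the complicating-factors
  system — witnessed apneas are the cardinal interview finding for OSA.

### Properties the defaults guarantee

`validate_cascade()` checks structure (term/variable references, the exact
(R1.a,R1.b)->R1, (R2.a,R2.b)->R2, (R1,R2)->preliminary wiring) and coverage
(a grid scan over each system's input box must never leave an empty
envelope). The test suite additionally verifies, for every system:

* **Monotonicity** on the reachable input lattice — 5 points on the
  continuous axes (hours, minutes) and the full category set on the discrete
  answer scales. More severe answers never lower a risk (tolerance `1e-4`
  for grid discretisation). Fractional values of categorical answers (e.g.
  nocturia = 2.5) are not reachable through the interview encoding and are
  not part of the guarantee; between category planes the min/max calculus
  can wiggle by a few hundredths, which is invisible at the category points
  the system actually receives.
* **Corner behaviour**: all answers at their most benign give a preliminary
  risk below 2; all answers at their most severe give above 8.
* **Determinism**: identical inputs give identical `CascadeResult`s.

On the shipped defaults the worked single-patient example
(`case_study_patient()`) produces R1.a = 6.25, R1.b = 1.25, R2.a = 8.75,
R2.b = 7.5, R1 = 3.75, R2 = 8.75 and a Symbolic Risk of 62.5 — the same
qualitative pattern (high snoring/apnea risks, low unrefreshing-sleep risk,
overall level 2) as the published account of that patient, whose exact
intermediate values depend on an unpublished full rule base.

## The statistical branch

The objective pipeline is: derive BMI (`weight / (height/100)^2`) and the
pack-year index (`cigarettes/day x years / 20`), which *replace* their raw
source fields; min-max normalize the numerics against fixed clinical bounds
(age 18-100 y, BMI 10-80 kg/m2, neck 25-60 cm, pack-years 0-150, alcohol
0-300 g/day — declared in `default_encoding_schema()` and overridable, since
the original clinician-set bounds are not published); dummy-encode each
c-category variable into c-1 indicators with an all-zero reference category;
label by AHI >= 15 (boundary inclusive, configurable); balance with SMOTE-NC;
and train bagged trees with stratified 5-fold cross-validation.

**SMOTE-NC.** Both classes are oversampled to a common target (default 4000
per class, k = 5 neighbours). Distances are Euclidean over the continuous
features plus a penalty of the median continuous-feature standard deviation
per mismatching categorical feature; synthetic rows interpolate continuous
features between a seed record and one of its k nearest same-class
neighbours and take categorical features by majority vote among those
neighbours. Whether balancing ran before or inside cross-validation is not
something the source protocol states, and it matters: balancing before the
split leaks synthetic copies of validation-fold records into training. The
default therefore balances *inside* each training fold, and the model object
reports both AUCs side by side (`glance()` columns `auc` and
`auc_prebalanced`); on synthetic cohorts the pre-balanced estimate is
visibly optimistic (~0.9 vs ~0.84).

**Learner.** Bagged trees are bootstrap-aggregated decision trees — a random
forest with no feature subsampling (`mtry = p`, full bootstrap resamples),
30 trees by default. The choice of learner is deliberately replaceable; the
branch's contract is only "a calibrated probability of OSA", reported as
`statistical_risk = 100 x P(OSA)`. Permutation importance is computed at fit
time so planted-signal recovery can be audited.

## Fusion

Each risk maps to a level against its branch thresholds: level 1 below
Limit 1, level 2 on `[L1, L2)` (closed left, open right), level 3 at or
above Limit 2. Defaults: L1 = 45 for both branches, L2 = 60 (statistical)
and 65 (symbolic); both are policy values meant to be reviewed. Levels score
0/1/2 points and

\[ T = W_{ST} \cdot \text{score}_{ST} + W_{SY} \cdot \text{score}_{SY},
\qquad W_{ST} = 2 - W_{SY},\; W_{ST}, W_{SY} \in [0, 2], \]

with unit weights by default, under which `T` enumerates {0, 1, 2, 3, 4}
over the nine level pairs. The recommendation is non-OSA (green) for
`T < 2`, doubtful (orange) for `2 <= T < 3`, possible OSA (red) for
`T >= 3`. The canonical rule says exactly `T = 2` for the doubtful case;
fractional `T` in `(2, 3)` is reachable only under non-unit weights and is
mapped to doubtful — the half-open interval preserves a total three-way
partition and errs toward clinical review. The partition is verified over
all nine score pairs crossed with a grid of valid weights.

## The synthetic cohort generator

No patient-level data are published, so the package ships a generator whose
defaults emulate the *study conditions*: a referred sleep-unit population of
n = 4400 with 61.2% of patients at AHI >= 15. It is a declared generative
model, not an imitation of any real cohort:

* Objective marginals: 70% male; age ~ N(55, 13) truncated to 18-95; BMI
  lognormal around 29 kg/m2; neck circumference increasing in BMI and male
  sex; smoking/drinking habits with plausible frequencies; comorbidity flags
  with age/BMI-dependent odds. Treatment flags are drawn independently of
  everything else, so they are pure-noise features against which planted
  signals can be ranked.
* AHI: `log(AHI + 1)` is linear in centred BMI, neck, age, male sex,
  hypertension and diabetes with Gaussian noise (sigma = 0.75); the
  intercept is calibrated by root-finding so the expected prevalence of
  AHI >= 15 matches the target. `ground_truth()` returns each record's true
  probability under this model, enabling calibration tests.
* Symptoms: each interview item is drawn from an ordered-logit latent with a
  per-item slope on the standardized log-AHI scale — witnessed apneas couple
  strongest (1.4), then snoring items, breathless awakenings and nocturia;
  hours of sleep and sleep latency couple weakly and negatively.

Effect sizes were fixed once, by design calculation, to give the
discriminability the study conditions imply (cross-validated AUC above 0.8
for the objective branch at n = 4400; rank correlation above 0.3 between the
Symbolic Risk and AHI) while remaining in the range of published clinical
associations. What passing tests on this cohort shows is that the *pipeline*
recovers planted structure of realistic strength and shape; it does not show
hospital-data performance, which depends on the real covariate structure and
the real expert rule base, neither of which is available.

## Numerical choices and problem sizes

* Defuzzification grid: 1001 points per output universe; doubling changes
  outputs by < 0.01 (tested). Oracle agreement with closed-form trapezoid
  centroids: `1e-6` at grid 10001.
* Cascade evaluation: ~16 ms per patient; cohort-scale checks in the test
  suite use n = 400-4400.
* Classifier checks run at n = 600 (unit tests) and n = 4400 with the full
  4000-per-class balancing (system tests), 15-30 trees; the label-permuted
  null control is required to land in AUC [0.45, 0.55].
* SMOTE-NC distance matrices are dense (n^2 per class); at the reference
  class sizes (2693/1707) this is ~60 MB and runs in seconds.
* All randomness (cohort draws, balancing, fold assignment, tree bootstraps)
  flows from explicit integer seeds; identical seeds reproduce results
  byte-for-byte, which the suite asserts end to end.

## Known limitations

* The shipped rule bases and membership functions are principled defaults
  consistent with the printed example rules, not the unpublished clinical
  knowledge base; absolute Symbolic Risk values should be re-calibrated
  against local clinical judgment before any real use (the JSON config
  round-trip exists for exactly that).
* The Statistical Risk is an uncalibrated ensemble vote fraction; treating
  it as a percentage risk assumes the training prevalence matches the
  deployment population.
* The generator's covariate correlations are assumptions; real sleep-unit
  cohorts have richer structure (e.g. referral bias, correlated
  comorbidities) that synthetic tests cannot exercise.
* Levels, scores and thresholds make the decision variable coarse by
  design; patients just under a limit are indistinguishable from patients
  far from it at the recommendation stage (the underlying risks are kept in
  the output for that reason).
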