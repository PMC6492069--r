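# circamood

Daily circadian features from passively collected device streams, and
rolling-origin evaluation of mood-state / mood-episode classifiers built
on them.

## Who this is for

Researchers in psychiatric digital phenotyping who want a tested,
reproducible reference pipeline for the question: *can near-future mood in
patients with mood disorders be predicted from wearable and phone sensors
alone* — minute heart rate, minute steps, ambient light, nightly sleep
records — *without using any self-reported mood as a predictor?* Since
cohorts of this kind are rarely shareable, the package also ships a
synthetic cohort generator with known ground truth so the whole pipeline
is testable end to end.

## The model at the core

Each patient-day is summarized by **13 basic circadian features** in four
families — steps and mean lux inside two **sunrise-anchored timeslots**
(daytime `[sunrise, sunset)`; bedtime = the 8 h ending at sunrise), sleep
length/efficiency and the **circular deviation** of sleep onset/offset
clock times from their trailing 7-day circular mean, plus the four
parameters of a 24-h **cosinor** fit

&nbsp;&nbsp;&nbsp;&nbsp;y(t) = M + A·cos(2π(t − φ)/24) + ε

(mesor M, amplitude A, acrophase φ, R²) over the 48 h of heart rate ending
with the day, and the day's resting heart rate. Each basic feature is
extended with trailing 3/6/12-day mean, sample SD and OLS gradient —
**130 features per day**. Rows with any missing value among the 130
features plus the mood score are dropped whole.

Labels: AMS = |daily mood score| (0–3); a day is *biased* when its forward
3-day mean AMS falls in the top 10/30/50% of the reference distribution,
*neutral* otherwise; 4-class episode labels (NE/DE/ME/HME) come from
clinician-style intervals. A random forest (authored in-package, compiled)
is evaluated **rolling-origin**: train on days `[t−p, t]`, test on
`[t+1, t+q]`, advance t — training never sees the future, and by default
the labeling threshold is computed inside each training window. Reported
metrics are round-averaged sensitivity, specificity, accuracy and
rank-statistic AUC, with signed (Pearson-vs-AMS) feature importances,
family ablations, and a general-vs-personalized model comparison.

## Worked example

```r
library(circamood)

# a small synthetic cohort: 3 patients, 90 days, coupled world
cohort <- simulate_cohort(sim_config(n_patients = 3, n_days = 90, seed = 1))
features <- build_feature_matrix(cohort$bundles)
labeled  <- filter_complete_rows(
  build_labeled_matrix(features, cohort$bundles, cutoff_pct = 50))

report <- rolling_evaluate(labeled, rolling_scheme(p = 18, q = 3),
                           label_spec("mood_state", cutoff = 50),
                           rf = list(ntree = 200, seed = 1),
                           keep_importance = TRUE)
report
#> <cm_eval_report> mood state, 50% cutoff: 18 rounds (0 skipped), p=18 q=3 step=3
#>   sensitivity  0.808 (SD 0.193)
#>   specificity  0.594 (SD 0.337)
#>   accuracy     0.691 (SD 0.204)
#>   auc          0.704 (SD 0.210)

head(feature_importance_with_direction(report, labeled, aggregate = TRUE), 4)
#>                 feature importance         sd   pearson_r  direction
#>                  <char>      <num>      <num>       <num>     <char>
#> 1:      HR_CR_amplitude 0.11950780 0.04110939 0.020998787 undirected
#> 2:          HR_CR_mesor 0.09735816 0.02577010 0.002864992 undirected
#> 3: steps_during_daytime 0.08554832 0.02755516 0.342612030   positive
#> 4:      HR_CR_acrophase 0.08420881 0.02243720 0.111069305   positive
```

Reading the output: over 18 evaluation rounds the forest labels unseen
future days with ~69% accuracy and AUC ~0.70 — above chance because in
this simulated world mood instability genuinely disrupts the sensors
(`coupling = 1`). In the importance table, daytime steps and the
heart-rate acrophase carry *directed* signal (positively correlated with
mood instability, matching the disruption directions the generator
encodes), while the gray/undirected mesor and amplitude entries mostly
reflect patient identity — the forest also exploits between-patient trait
differences, a caveat the methods vignette discusses. (Exact numbers come
from the seed shown; your machine will reproduce them.)

The same stages are scriptable end to end:

```sh
Rscript -e 'circamood::cm_main()' simulate --config run.yaml --out runs/raw
Rscript -e 'circamood::cm_main()' extract  --config run.yaml --input runs/raw --out runs/feat
```

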