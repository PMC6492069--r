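---
title: "Circadian features and rolling mood prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian features and rolling mood prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circamood)
```

## The problem

Mood disorders are characterized by recurrent episodes and by disturbances
of the circadian system: shifted heart-rate rhythms, irregular sleep-wake
timing, and displaced activity and light exposure. `circamood` implements a
complete pipeline that turns passively collected device streams — minute
heart rate, minute step counts, light-sensor samples, nightly sleep records
— into daily circadian features and evaluates how well near-future mood can
be predicted from them, without using any self-reported mood as a
predictor.

Because the kind of clinical cohort this design targets is not publicly
available, the package ships a synthetic cohort generator with known ground
truth; every downstream stage is tested against it.

## Solar timeslots

All activity and light features are anchored to the sun, not the clock,
because early-morning light is the dominant zeitgeber. For each civil day
`d`:

* **daytime** = `[sunrise(d), sunset(d))`;
* **bedtime** = the fixed 8-hour block ending at a sunrise — constant
  duration, seasonally moving placement.

Sunrise and sunset come from the standard NOAA low-precision solar
formulas (fractional-year Fourier series for the equation of time and the
solar declination, hour angle at the official zenith of 90.833°), accurate
to a few minutes at mid-latitudes; sites beyond ±66° latitude are refused.
A user-supplied `suntimes.csv` overrides the computation verbatim.

One anchoring ambiguity deserves a note. "Bedtime of day `d`" could be the
night *following* day `d` (ending at `sunrise(d+1)`) or the night *ending*
on day `d`'s morning. The window constructor `bedtime_window(d)` uses the
next-day anchor, but the **features attributed to day `d` use the night
ending at `sunrise(d)`** — the same night whose sleep record is attributed
to day `d` (its wake-up date). This is the only assignment under which
every feature of day `d` is computable at the end of day `d`, which the
anti-leakage audit enforces; with the other anchor, "today's" bedtime
activity would not exist until tomorrow morning.

## The 13 basic features

| feature | unit | definition |
|---|---|---|
| steps_during_bedtime / _daytime | steps | total steps inside the slot |
| light_exposure_during_bedtime / _daytime | lux | mean of light samples inside the slot |
| sleep_length | h | offset − onset of the night attributed to the day |
| sleep_efficiency | % | as reported by the tracker |
| sleep_onset_dev / sleep_offset_dev | h | circular deviation of today's clock time from the trailing 7-day circular mean (≥ 3 records required) |
| HR_CR_mesor / amplitude / acrophase / rsquared | bpm, bpm, h, – | 24-h cosinor over the 48 h ending with the day |
| resting_heart_rate | bpm | minimum of the 5-minute rolling mean of the day's HR |

Conventions that the source design left open, pinned here and exposed as
arguments:

* **Sleep-timing regularity** is the absolute circular deviation (24-h
  circle) from the circular mean of the preceding 7 days; a 23:00 → 01:00
  shift counts as 2 h, never 22 h. Window length and the 3-record minimum
  are configurable.
* **Resting heart rate** smooths with a 5-minute rolling mean before
  taking the minimum, so a single artifactually low sample cannot define
  the day.
* **Cosinor window**: the 48 h covering days `d−1` and `d` (never `d+1`),
  fit by OLS of `y = M + β₁cos(ωt) + β₂sin(ωt)` with `ω = 2π/24 h⁻¹`;
  amplitude `= √(β₁²+β₂²)`, acrophase `= atan2(β₂, β₁)/ω mod 24` reported
  as clock time of the peak. A fit requires at least 1440 samples (half
  the expected minute grid); constant series return amplitude 0, missing
  acrophase, R² 0.
* **Missing slots**: a *mean* over an empty slot is missing; a step *sum*
  over an empty slot is 0 when the tracker produced data on the slot's
  civil days (worn but stationary) and missing when it produced none
  (day-granular removal).

## Extended features

Each basic feature is extended with its trailing 3-, 6- and 12-day window
mean, sample SD (denominator `w−1`) and OLS gradient against day index
(units: per day); the window for day `d` covers days `d−w+1 … d`. A window
statistic is missing if any constituent day is, mirroring the strict
complete-row policy. That yields 13 + 13×3×3 = **130 columns per
patient-day**. Acrophase series are unwrapped along the shortest arc before
windowed statistics (a 23.9 → 0.1 transition is a 0.2-h change, not
−23.8), and the windowed acrophase mean is mapped back to `[0, 24)`.

Rows with any missing value among the 130 features plus the mood score are
dropped whole (`filter_complete_rows()`), with per-family missingness
accounting; nothing is imputed.

## Labels

The daily self-rated mood score (−3 … +3) folds into the **absolute mood
score** AMS = |score| (0 … 3, higher = less stable in either direction).
The 2-class **mood state** of day `d` is defined from the mean AMS of days
`d+1 … d+3` (present only when all three exist): days in the top 10/30/50%
of the reference distribution are *biased*, the rest *neutral*. The
threshold is the order statistic `x(k)`, `k = floor(n(1−c/100)) + 1`, with
ties going to *biased* — pinned so a sort-based oracle reproduces labels
exactly. By default the reference distribution is each evaluation round's
*training window* (leak-free); `reference = "global"` reproduces
whole-data thresholding. The 4-class **episode** label (NE/DE/ME/HME)
comes from clinician-style intervals, NE outside all of them.

## Models and evaluation

The learner is a random forest — bagged CART trees, Gini impurity,
`mtry = ⌊√p⌋` features per split, trees grown to purity, 500 trees by
default — implemented in compiled code inside the package because the
target environment provides no forest implementation. Probabilities
average leaf class distributions; importances are normalized
mean-decrease-in-impurity. Training is bit-reproducible from an integer
seed; per-round seeds are derived from the global seed and round index.

**Rolling-origin evaluation**: sort by date; for origin `t`, train on days
`[t−p, t]`, test on `[t+1, t+q]`, advance `t` by `q` (configurable).
Rounds with single-class training windows are skipped and counted, never
zero-filled. Sensitivity, specificity, accuracy and rank-statistic AUC
(exactly the normalized Mann-Whitney pairwise count) are averaged over
rounds. An audit asserts `max(train dates) < min(test dates)` in every
round. Episode prediction fits one 4-class forest and reports one-vs-rest
metrics per target class. The `(p, q)` sweep selects by mean accuracy
(AUC available as an option, since the source design did not state its
criterion).

The **general vs personalized** comparison trains, per patient, one forest
on all other patients' rows (the general model) and evaluates it on the
same test windows as the patient's own rolling evaluation (the
personalized model); reported are per-patient accuracies, the fraction of
patients where personalization wins, and the mean advantage.

Class imbalance is left unadjusted by default, mirroring the source
design's caveat; ablations remove one of the four feature families (a
family takes its basic features and all nine window statistics each:
steps 20, light 20, sleep 40, heart-rate 50 columns).

## The synthetic cohort: what it emulates, and what a green test means

Defaults state the emulated world: 55 patients, up to 730 days, a
Seoul-like site (UTC+9). Per patient-day a four-state Markov chain
(NE/DE/ME/HME; stationary occupancy ≈ 82/12/1/4%, sojourns of roughly a
month) drives a latent *instability* in `[0,1]` through an AR(1) filter
(`ρ = 0.8`, innovation SD 0.25 before filtering) — temporally smooth mood
with regime structure, which is exactly the premise that recent days
predict the near future. The mood score is
`round(polarity · 3 · instability + ε)` clipped to ±3, `ε ∈ {−1,0,1}`
with `P(±1) = 0.15`; polarity is −1 in DE, +1 in ME/HME, a random sign in
NE.

`coupling ≥ 0` scales how instability disrupts the sensors: bedtime step
rate and bedtime lux up, daytime step rate and lux down, sleep-timing
jitter up, HR acrophase delayed by `coupling × instability` hours.
Distributions are explicit artifact choices (Poisson steps, log-normal
lux, Gaussian HR noise and sleep jitter), documented here and not claims
about any real cohort. Two forms of realistic heterogeneity matter for
honest evaluation:

* **day-level behavioral noise** (log-normal multiplier, SD 0.25 on the
  log scale, on activity and light): without it, daytime step totals track
  the seasonal daylength almost deterministically, the calendar date
  becomes readable from the features, and even a decoupled world shows
  AUC > 0.5 through date alone;
* **patient-level trait offsets** (mesor ± 3 bpm, acrophase and habitual
  sleep time ± 0.75 h, activity scale ± 20%), scaled by `patient_hetero`.

Even so, a pooled rolling evaluation of a *decoupled* (`coupling = 0`)
world is **not** guaranteed AUC 0.5: mood remains autocorrelated within
patient, patients are identifiable from their trait offsets, and a forest
can ride identity plus recency without any sensor-mood coupling. That is
a genuine property of pooled longitudinal evaluation, not a leak — the
clean null is obtained by permuting labels, which the null-behavior tests
use; the decoupled world is tested for what it actually guarantees (no
*within-patient* mood signal in the sensors). A green coupled-world test
establishes that the pipeline detects the simulated circadian-disruption
signature; it does not establish clinical effect sizes, and no real-data
accuracy is reproduced anywhere in this package.

Missingness is injected per stream at day granularity (a tracker removed
for a whole day), matching the complete-row filter's granularity.

## Numerical choices and degenerate inputs

* Timestamps are ISO-8601 with explicit UTC offset; all internal time
  arithmetic is in the site's fixed-offset civil time (no DST ambiguity).
* Windows are half-open `[start, end)`; a boundary sample belongs to
  exactly one window.
* Cosinor: SST = 0 (constant input) gives amplitude 0 and R² 0 rather
  than NaN; rank-deficient designs return an all-missing fit.
* The AUC is computed from ranks with mean-rank tie handling, so it equals
  the brute-force pairwise count exactly, ties counting ½.
* Forest determinism comes from an internal splitmix64/xorshift RNG,
  independent of R's RNG state.
* Tests run on deliberately small cohorts (2–6 patients, 45–100 days) to
  fit CI budgets; the generator's *defaults* remain the full stated world.

## Known limitations

* The forest has no class-weighting enabled by default; rare-episode
  sensitivity is correspondingly low, as in the source design.
* The solar routine ignores refraction anomalies and altitude; accuracy is
  a few minutes, adequate for 8-h windows.
* Light "exposure" is raw mean lux; no normalization or log-transform is
  applied at the feature stage.
* The generator couples all four sensor families to a single latent
  instability; real disorders likely have channel-specific dynamics.
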