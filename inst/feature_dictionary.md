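# Feature dictionary

130 predictor columns per patient-day: 13 basic features plus, for every
basic feature, the trailing-window statistics `<basic>_<w>d_<stat>` with
`w ∈ {3, 6, 12}` days and `stat ∈ {mean, stdev, gradient}`.

## Basic features (13)

| name | unit | family | definition |
|---|---|---|---|
| steps_during_bedtime | steps | steps | total steps in the 8-h bedtime slot ending at the day's sunrise; 0 if the tracker recorded that day but saw no steps, missing if the stream is absent for the slot's civil days |
| steps_during_daytime | steps | steps | total steps in `[sunrise, sunset)` of the day |
| light_exposure_during_bedtime | lux | light | mean lux of samples in the bedtime slot; missing if no samples |
| light_exposure_during_daytime | lux | light | mean lux of samples in the daytime slot; missing if no samples |
| sleep_length | hours | sleep | offset − onset of the sleep record attributed to the day (wake-up date) |
| sleep_efficiency | percent | sleep | tracker-reported efficiency of that record |
| sleep_onset_dev | hours | sleep | absolute circular deviation (24-h clock) of today's onset clock time from the circular mean of the preceding 7 days (≥ 3 records required) |
| sleep_offset_dev | hours | sleep | same, for the offset |
| HR_CR_amplitude | bpm | heart-rate | amplitude of the 24-h cosinor over the 48 h covering days d−1 and d |
| HR_CR_acrophase | clock hours | heart-rate | clock time of the fitted peak, in [0, 24) |
| HR_CR_mesor | bpm | heart-rate | rhythm-adjusted mean of the fit |
| HR_CR_rsquared | fraction | heart-rate | 1 − SSE/SST of the fit (0 for a constant series) |
| resting_heart_rate | bpm | heart-rate | minimum of the 5-minute rolling mean of the day's HR samples |

Cosinor fits require ≥ 1440 samples (half the expected minute grid for
48 h); all heart-rate fields are missing otherwise.

## Window statistics (117)

For day `d` and window `w`, the statistic is computed over the basic
feature's values on days `d−w+1 … d` (calendar days; a statistic is
missing if any constituent day's basic value is missing):

* `mean` — arithmetic mean;
* `stdev` — sample SD, denominator `w − 1`;
* `gradient` — OLS slope of value against day index, units per day.

`HR_CR_acrophase` is unwrapped along the shortest arc before windowing so
the 0/24 boundary creates no artifacts; its windowed `mean` is reported
modulo 24 (stdev and gradient are left on the unwrapped scale).

## Family membership (used for ablation and missingness accounting)

* steps: 2 basic × 10 columns = 20
* light: 2 × 10 = 20
* sleep: 4 × 10 = 40
* heart-rate: 5 × 10 = 50
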