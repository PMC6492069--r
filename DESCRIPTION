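Package: circamood
Title: Circadian Digital-Phenotype Features and Mood-State Prediction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds daily circadian features from passively collected
    wearable and smartphone streams (minute-level heart rate and steps,
    light-sensor samples, nightly sleep records) and evaluates mood-state
    and mood-episode classifiers under a rolling-origin temporal scheme.
    Includes sunrise-anchored bedtime/daytime timeslots via a NOAA-style
    solar routine, 24-h cosinor analysis of 48-h heart-rate windows,
    sleep-regularity statistics, a 130-column feature matrix (13 basic
    features extended by 3/6/12-day mean/SD/gradient), absolute-mood-score
    labeling, a compiled random-forest learner with impurity importances,
    feature-family ablations, a general-versus-personalized model
    comparison, and a synthetic cohort generator with known ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
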