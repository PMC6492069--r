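# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small noisy cohort shared by feature/labeling/modeling tests
small_cohort <- function() {
  cached("small_cohort",
         simulate_cohort(sim_config(n_patients = 2, n_days = 60, seed = 42)))
}

small_labeled <- function() {
  cached("small_labeled", {
    co <- small_cohort()
    fm <- build_feature_matrix(co$bundles)
    lm <- build_labeled_matrix(fm, co$bundles, cutoff_pct = 50)
    suppressMessages(filter_complete_rows(lm))
  })
}

# single noiseless, uncoupled, homogeneous patient: every derived quantity
# is known in closed form
noiseless_cohort <- function() {
  cached("noiseless_cohort",
         simulate_cohort(sim_config(
           n_patients = 1, n_days = 16, hr_noise_sd = 0, coupling = 0,
           patient_hetero = 0, day_noise_sd = 0, sleep_jitter_sd = 0,
           seed = 11)))
}

test_site <- function() cm_site(37.5665, 126.9780, 9)

# independent oracle: AUC by brute-force pairwise comparison
auc_pairwise_oracle <- function(scores, is_pos) {
  p <- scores[is_pos]; n <- scores[!is_pos]
  if (!length(p) || !length(n)) return(NA_real_)
  tot <- 0
  for (x in p) tot <- tot + sum(x > n) + 0.5 * sum(x == n)
  tot / (length(p) * length(n))
}
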