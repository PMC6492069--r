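test_that("confusion arithmetic matches hand counts", {
  truth <- c(rep("pos", 10), rep("neg", 10))
  pred <- c(rep("pos", 9), "neg", rep("neg", 8), "pos", "pos")
  scores <- c(seq(0.9, 0.5, length.out = 10), seq(0.4, 0.1, length.out = 8), 0.8, 0.7)
  m <- compute_metrics(truth, pred, scores, "pos")
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$n_test, 20)
})

test_that("AUC equals the brute-force pairwise oracle, exactly", {
  # perfectly separated
  m <- compute_metrics(c("p", "p", "n", "n"), c("p", "p", "n", "n"),
                       c(0.9, 0.8, 0.2, 0.1), "p")
  expect_identical(m$auc, 1)
  set.seed(88)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    # coarse scores force ties, which the oracle counts as 1/2
    scores <- round(runif(n), 1)
    got <- compute_metrics(truth, truth, scores, TRUE)$auc
    expect_identical(got, auc_pairwise_oracle(scores, truth))
  }
  # single-class truth: AUC undefined
  expect_true(is.na(compute_metrics(rep("p", 5), rep("p", 5), runif(5), "p")$auc))
})

test_that("round structure matches an independent enumeration", {
  lab <- small_labeled()
  # restrict to label-eligible rows, as the evaluator does
  one <- lab[patient_id == lab$patient_id[1] & !is.na(fwd3_ams)]
  scheme <- rolling_scheme(18, 3, step = 3)
  rep <- rolling_evaluate(one, scheme, label_spec(),
                          rf = list(ntree = 20, seed = 1))
  # oracle: enumerate candidate origins over the complete-row date span
  dmin <- min(one$date); dmax <- max(one$date)
  t_cands <- seq(dmin + 18, dmax - 3, by = 3)
  valid <- vapply(t_cands, function(t) {
    tr <- one[date >= t - 18 & date <= t]
    te <- one[date >= t + 1 & date <= t + 3]
    thr_ok <- nrow(tr) > 0 && nrow(te) > 0
    if (!thr_ok) return(FALSE)
    thr <- sort(tr$fwd3_ams)[floor(nrow(tr) * 0.5) + 1]
    length(unique(tr$fwd3_ams >= thr)) == 2
  }, logical(1))
  expect_equal(rep$n_rounds + rep$n_skipped, length(t_cands))
  expect_equal(rep$n_rounds, sum(valid))
})

test_that("no round trains on the future, across a sweep", {
  lab <- small_labeled()
  for (p in c(6, 12, 18)) {
    for (q in c(3, 6)) {
      rep <- rolling_evaluate(lab, rolling_scheme(p, q), label_spec(),
                              rf = list(ntree = 10, seed = 1))
      expect_true(all(rep$rounds$train_max < rep$rounds$test_min),
                  label = sprintf("p=%d q=%d", p, q))
      expect_true(all(rep$rounds$train_min >= rep$rounds$t - p))
      expect_true(all(rep$rounds$test_max <= rep$rounds$t + q))
    }
  }
})

test_that("rolling evaluation is deterministic and order-invariant", {
  lab <- small_labeled()
  r1 <- rolling_evaluate(lab, rolling_scheme(18, 3), label_spec(),
                         rf = list(ntree = 30, seed = 9))
  r2 <- rolling_evaluate(lab, rolling_scheme(18, 3), label_spec(),
                         rf = list(ntree = 30, seed = 9))
  expect_identical(r1$rounds, r2$rounds)
  # shuffling input row order must not change the averaged metrics
  shuf <- lab[sample(nrow(lab))]
  r3 <- rolling_evaluate(shuf, rolling_scheme(18, 3), label_spec(),
                         rf = list(ntree = 30, seed = 9))
  expect_equal(r3$summary$accuracy[["mean"]], r1$summary$accuracy[["mean"]])
})

test_that("episode one-vs-rest metrics come from a multiclass forest", {
  lab <- copy(small_labeled())
  # engineer a visible DE regime so the 4-class path is exercised
  lab[, episode := factor(fifelse(seq_len(.N) %% 7 < 2, "DE", "NE"),
                          levels = c("NE", "DE", "ME", "HME"))]
  rep <- rolling_evaluate(lab, rolling_scheme(18, 3),
                          label_spec(type = "episode", target = "DE"),
                          rf = list(ntree = 30, seed = 2))
  expect_gt(rep$n_rounds, 0)
  expect_true(all(rep$rounds$accuracy >= 0 & rep$rounds$accuracy <= 1))
})

test_that("p/q sweep returns the argmax and degenerates sanely", {
  lab <- small_labeled()
  sw <- sweep_pq(lab, p_values = c(12, 18), q_values = 3,
                 rf = list(ntree = 20, seed = 1))
  expect_equal(nrow(sw$grid), 2)
  expect_equal(sw$best$accuracy, max(sw$grid$accuracy, na.rm = TRUE))
  # grid restricted to one pair: argmax is that pair
  sw1 <- sweep_pq(lab, p_values = 18, q_values = 3,
                  rf = list(ntree = 20, seed = 1))
  expect_equal(c(sw1$best$p, sw1$best$q), c(18L, 3L))
  # determinism
  sw2 <- sweep_pq(lab, p_values = 18, q_values = 3,
                  rf = list(ntree = 20, seed = 1))
  expect_identical(sw1$grid, sw2$grid)
})

test_that("importance direction uses the 0.1 Pearson threshold", {
  set.seed(12)
  n <- 300
  ams <- sample(0:3, n, replace = TRUE)
  mat <- data.table(ams = ams,
                    mirror = ams,                        # r = 1
                    inverse = -ams + rnorm(n, 0, 0.1),   # r ~ -1
                    noise = rnorm(n))                    # |r| < 0.1
  fake <- structure(list(importance = data.table(
    feature = c("mirror", "inverse", "noise"),
    importance = c(2, 1, 1), sd = c(0, 0, 0))), class = "cm_eval_report")
  imp <- feature_importance_with_direction(fake, mat)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_identical(imp[feature == "mirror", direction], "positive")
  expect_equal(imp[feature == "mirror", pearson_r], 1)
  expect_identical(imp[feature == "inverse", direction], "negative")
  expect_identical(imp[feature == "noise", direction], "undirected")
})

test_that("importances from a rolling report aggregate to basic families", {
  lab <- small_labeled()
  rep <- rolling_evaluate(lab, rolling_scheme(18, 3), label_spec(),
                          rf = list(ntree = 30, seed = 4),
                          keep_importance = TRUE)
  imp <- feature_importance_with_direction(rep, lab)
  expect_equal(nrow(imp), 130)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  agg <- feature_importance_with_direction(rep, lab, aggregate = TRUE)
  expect_equal(nrow(agg), 13)
  expect_equal(sum(agg$importance), 1, tolerance = 1e-9)
})

test_that("family ablation removes the right columns and guards its domain", {
  lab <- small_labeled()
  scheme <- rolling_scheme(18, 3)
  base <- rolling_evaluate(lab, scheme, rf = list(ntree = 20, seed = 1))
  ab <- ablate_family(lab, "steps", scheme, rf = list(ntree = 20, seed = 1),
                      baseline = base)
  expect_length(ab$removed, 20) # 2 basic x (1 + 9 window stats)
  ab_sl <- ablate_family(lab, "sleep", scheme, rf = list(ntree = 20, seed = 1),
                         baseline = base)
  expect_length(ab_sl$removed, 40)
  ab_hr <- ablate_family(lab, "heart-rate", scheme, rf = list(ntree = 20, seed = 1),
                         baseline = base)
  expect_length(ab_hr$removed, 50)
  expect_error(ablate_family(lab, "gps", scheme), "unknown feature family")
  expect_error(ablate_family(lab, names(circamood:::FEATURE_FAMILIES), scheme),
               "no predictors")
})

test_that("general vs personalized comparison runs per patient", {
  lab <- small_labeled()
  expect_error(compare_general_personalized(lab[patient_id == lab$patient_id[1]],
                                            rolling_scheme(18, 3)),
               "single patient")
  cmp <- compare_general_personalized(lab, rolling_scheme(18, 3),
                                      rf = list(ntree = 30, seed = 1))
  expect_equal(nrow(cmp$per_patient), 2)
  expect_true(all(cmp$per_patient$acc_personalized >= 0 &
                    cmp$per_patient$acc_personalized <= 1))
  expect_true(all(cmp$per_patient$acc_general >= 0 &
                    cmp$per_patient$acc_general <= 1))
  expect_equal(cmp$per_patient$advantage,
               cmp$per_patient$acc_personalized - cmp$per_patient$acc_general)
})
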