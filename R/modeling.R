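# Rolling-origin evaluation of mood-state / episode classifiers.
#
# For an origin day t, a forest is trained on rows with date in [t-p, t]
# and tested on rows in [t+1, t+q]; t advances (by q, by default) from the
# beginning to the end of the timeline, and reported metrics are averages
# over the rounds. Training never sees dates after t, and mood-state
# thresholds are, by default, computed inside each training window so that
# labels cannot leak test information either.

#' Rolling-origin scheme
#'
#' @param p Training-window length in days.
#' @param q Test-window length in days.
#' @param step Days by which the origin advances between rounds; default
#'   `q` (non-overlapping test windows).
#' @return List of class `cm_scheme`.
#' @export
rolling_scheme <- function(p, q, step = q) {
  stopifnot(p >= 1, q >= 1, step >= 1)
  structure(list(p = as.integer(p), q = as.integer(q), step = as.integer(step)),
            class = "cm_scheme")
}

#' Label specification for evaluation
#'
#' @param type `"mood_state"` (2-class, forward 3-day AMS percentile) or
#'   `"episode"` (4-class with one-vs-rest metrics for `target`).
#' @param cutoff Mood-state upper-tail percentage (10/30/50).
#' @param reference `"train"` (threshold from each round's training window;
#'   leak-free default) or `"global"` (whole-matrix thresholding).
#' @param target Episode class whose one-vs-rest metrics are reported
#'   (NE/DE/ME/HME).
#' @return List of class `cm_label_spec`.
#' @export
label_spec <- function(type = c("mood_state", "episode"), cutoff = 50,
                       reference = c("train", "global"), target = "DE") {
  type <- match.arg(type)
  reference <- match.arg(reference)
  if (type == "episode" && !target %in% EPISODE_STATES) {
    stop("target must be one of ", paste(EPISODE_STATES, collapse = "/"))
  }
  structure(list(type = type, cutoff = cutoff, reference = reference,
                 target = target), class = "cm_label_spec")
}

# ---- metrics --------------------------------------------------------------

# Mann-Whitney AUC from ranks; ties get mean ranks. NA when either class
# is absent.
auc_rank <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/n, and
#' the rank-statistic AUC of the positive-class scores (equivalent to the
#' normalized Mann-Whitney pairwise-comparison count, ties counting 1/2).
#' For multi-class truths, all classes other than `positive_class` are
#' merged into the negative class (one-vs-rest).
#'
#' @param truth True labels (factor/character/logical).
#' @param predictions Predicted labels, same vocabulary.
#' @param scores Positive-class scores/probabilities.
#' @param positive_class Label counted as positive (default `TRUE` for
#'   logical truths).
#' @return List of class `cm_metrics`: sensitivity, specificity, accuracy,
#'   auc, n_test (AUC is `NA` for single-class truths).
#' @export
compute_metrics <- function(truth, predictions, scores,
                            positive_class = TRUE) {
  truth <- as.character(truth); predictions <- as.character(predictions)
  stopifnot(length(truth) == length(predictions),
            length(truth) == length(scores))
  pos <- truth == as.character(positive_class)
  ppos <- predictions == as.character(positive_class)
  tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
  tn <- sum(!pos & !ppos); fp <- sum(!pos & ppos)
  structure(list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(truth),
    auc = auc_rank(scores, pos),
    n_test = length(truth)), class = "cm_metrics")
}

# ---- rolling evaluation ---------------------------------------------------

round_seed <- function(seed, t_index) {
  as.integer((as.double(seed) * 48271 + 7919 * t_index) %% 2147483647)
}

prepare_model_rows <- function(matrix, label, features) {
  matrix <- as.data.table(matrix)
  miss <- setdiff(features, names(matrix))
  if (length(miss)) stop("matrix lacks feature column(s): ", paste(head(miss, 3), collapse = ", "))
  need <- if (label$type == "mood_state") "fwd3_ams" else "episode"
  if (!need %in% names(matrix)) stop("matrix lacks required column: ", need)
  ok <- stats::complete.cases(matrix[, ..features]) & !is.na(matrix[[need]])
  matrix[ok]
}

#' Evaluate a classifier under the rolling-origin scheme
#'
#' Trains one forest per round on the complete labeled rows of the
#' training window and scores the following test window; rounds whose
#' training window contains a single class (or whose windows are empty)
#' are skipped and counted. Metrics are averaged over completed rounds. An
#' internal audit asserts `max(train dates) < min(test dates)` for every
#' round.
#'
#' @param matrix Labeled feature matrix ([build_labeled_matrix()] output;
#'   rows with incomplete features or missing labels are dropped here).
#' @param scheme A [rolling_scheme()].
#' @param label A [label_spec()].
#' @param rf Forest configuration: list with `ntree`, `mtry`, `seed`
#'   (per-round seeds are derived from `seed` and the round index).
#' @param features Feature columns to use (default all 130); ablations
#'   pass a subset.
#' @param keep_importance Store per-round normalized importances.
#' @return Object of class `cm_eval_report`: `rounds` (per-round metrics
#'   and window bounds), `summary` (mean/SD of each metric), `n_rounds`,
#'   `n_skipped`, `scheme`, `label`, optionally `importance`.
#' @export
rolling_evaluate <- function(matrix, scheme, label = label_spec(),
                             rf = list(ntree = 500, mtry = NULL, seed = 1),
                             features = feature_names(),
                             keep_importance = FALSE) {
  stopifnot(inherits(scheme, "cm_scheme"), inherits(label, "cm_label_spec"))
  rows <- prepare_model_rows(matrix, label, features)
  if (!nrow(rows)) stop("no complete labeled rows to evaluate")
  # canonical order: results must not depend on input row order
  setorderv(rows, intersect(c("date", "patient_id"), names(rows)))

  global_thr <- NULL
  if (label$type == "mood_state" && label$reference == "global") {
    global_thr <- upper_tail_threshold(rows$fwd3_ams, label$cutoff)
  }

  dmin <- min(rows$date); dmax <- max(rows$date)
  t_seq <- seq(dmin + scheme$p, dmax - scheme$q, by = scheme$step)
  if (!length(t_seq)) stop("no valid evaluation rounds: timeline shorter than p + q")

  res <- list(); imps <- list(); n_skipped <- 0L
  ntree <- rf$ntree %||% 500; base_seed <- rf$seed %||% 1
  for (i in seq_along(t_seq)) {
    t <- t_seq[i]
    tr <- rows[date >= t - scheme$p & date <= t]
    te <- rows[date >= t + 1 & date <= t + scheme$q]
    if (!nrow(tr) || !nrow(te)) { n_skipped <- n_skipped + 1L; next }
    stopifnot(max(tr$date) < min(te$date)) # anti-leakage audit

    if (label$type == "mood_state") {
      thr <- if (is.null(global_thr)) upper_tail_threshold(tr$fwd3_ams, label$cutoff) else global_thr
      y_tr <- factor(fifelse(tr$fwd3_ams >= thr, "biased", "neutral"),
                     levels = c("neutral", "biased"))
      y_te <- factor(fifelse(te$fwd3_ams >= thr, "biased", "neutral"),
                     levels = c("neutral", "biased"))
      positive <- "biased"
    } else {
      y_tr <- factor(as.character(tr$episode), levels = EPISODE_STATES)
      y_te <- factor(as.character(te$episode), levels = EPISODE_STATES)
      positive <- label$target
    }
    if (length(unique(as.character(y_tr))) < 2L) { n_skipped <- n_skipped + 1L; next }

    fit <- cm_rf(tr[, ..features], y_tr, ntree = ntree, mtry = rf$mtry,
                 seed = round_seed(base_seed, i))
    pr <- predict(fit, te[, ..features], type = "prob")
    pred <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                   levels = levels(y_tr))
    score <- if (positive %in% colnames(pr)) pr[, positive] else rep(0, nrow(pr))
    m <- compute_metrics(y_te, pred, score, positive)
    res[[length(res) + 1L]] <- data.table(
      t = t, train_min = min(tr$date), train_max = max(tr$date),
      test_min = min(te$date), test_max = max(te$date),
      n_train = nrow(tr), n_test = nrow(te),
      sensitivity = m$sensitivity, specificity = m$specificity,
      accuracy = m$accuracy, auc = m$auc)
    if (keep_importance) imps[[length(imps) + 1L]] <- fit$importance
  }
  if (!length(res)) stop("no valid evaluation rounds (all skipped)")
  rounds <- rbindlist(res)

  msd <- function(x) c(mean = mean(x, na.rm = TRUE),
                       sd = if (sum(!is.na(x)) > 1) sd(x, na.rm = TRUE) else NA_real_)
  summary <- list(sensitivity = msd(rounds$sensitivity),
                  specificity = msd(rounds$specificity),
                  accuracy = msd(rounds$accuracy),
                  auc = msd(rounds$auc))
  importance <- NULL
  if (keep_importance && length(imps)) {
    im <- do.call(rbind, imps)
    importance <- data.table(feature = colnames(im),
                             importance = colMeans(im),
                             sd = apply(im, 2, sd))
  }
  structure(list(rounds = rounds, summary = summary,
                 n_rounds = nrow(rounds), n_skipped = n_skipped,
                 scheme = scheme, label = label, importance = importance),
            class = "cm_eval_report")
}

#' @export
print.cm_eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cm_eval_report> %s: %d rounds (%d skipped), p=%d q=%d step=%d\n",
              if (x$label$type == "mood_state")
                sprintf("mood state, %d%% cutoff", x$label$cutoff)
              else sprintf("episode %s vs rest", x$label$target),
              x$n_rounds, x$n_skipped, x$scheme$p, x$scheme$q, x$scheme$step))
  for (m in names(s)) {
    cat(sprintf("  %-12s %.3f (SD %.3f)\n", m, s[[m]]["mean"], s[[m]]["sd"]))
  }
  invisible(x)
}

#' Sweep training/test window lengths
#'
#' Evaluates every `(p, q)` pair on a configurable subgrid of the
#' 3..300-day training and 3..30-day test ranges and returns the pair that
#' maximizes the selection criterion (mean accuracy by default).
#'
#' @param matrix,label,rf As in [rolling_evaluate()].
#' @param p_values,q_values Integer vectors of window lengths to try.
#' @param criterion `"accuracy"` or `"auc"`.
#' @return List of class `cm_sweep`: `grid` (`data.table` with p, q,
#'   accuracy, auc, n_rounds), `best` (row maximizing the criterion),
#'   `criterion`.
#' @export
sweep_pq <- function(matrix, p_values = c(3, 6, 12, 18, 30, 60),
                     q_values = c(3, 6, 12), label = label_spec(),
                     rf = list(ntree = 500, seed = 1),
                     criterion = c("accuracy", "auc")) {
  criterion <- match.arg(criterion)
  stopifnot(all(p_values >= 1), all(q_values >= 1))
  grid <- CJ(p = as.integer(p_values), q = as.integer(q_values))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    rep <- tryCatch(
      rolling_evaluate(matrix, rolling_scheme(grid$p[i], grid$q[i]), label, rf),
      error = function(e) NULL)
    if (is.null(rep)) {
      return(data.table(p = grid$p[i], q = grid$q[i], accuracy = NA_real_,
                        auc = NA_real_, n_rounds = 0L))
    }
    data.table(p = grid$p[i], q = grid$q[i],
               accuracy = rep$summary$accuracy[["mean"]],
               auc = rep$summary$auc[["mean"]], n_rounds = rep$n_rounds)
  })
  g <- rbindlist(out)
  if (all(is.na(g[[criterion]]))) stop("no (p, q) pair produced a valid evaluation")
  best <- g[which.max(g[[criterion]])]
  structure(list(grid = g, best = best, criterion = criterion),
            class = "cm_sweep")
}

#' @export
print.cm_sweep <- function(x, ...) {
  cat(sprintf("<cm_sweep> %d pairs, best by %s: p=%d q=%d (%.3f)\n",
              nrow(x$grid), x$criterion, x$best$p, x$best$q,
              x$best[[x$criterion]]))
  invisible(x)
}

# ---- importance -----------------------------------------------------------

#' Signed feature importances
#'
#' Normalized impurity importances (from a single [cm_rf()] fit or
#' averaged over the rounds of a [rolling_evaluate()] report run with
#' `keep_importance = TRUE`) with a direction attached: the sign of the
#' Pearson correlation between the feature and the day's AMS, reported as
#' `undirected` when `|r| < 0.1` (or the feature is constant).
#'
#' @param x A `cm_rf` or `cm_eval_report`.
#' @param matrix Labeled matrix providing feature values and `ams`.
#' @param aggregate If `TRUE`, sum member importances into the 13 basic
#'   features (a basic feature and its nine window statistics form one
#'   group).
#' @return `data.table(feature, importance[, sd], pearson_r, direction)`,
#'   sorted by decreasing importance; importances sum to 1.
#' @export
feature_importance_with_direction <- function(x, matrix, aggregate = FALSE) {
  if (inherits(x, "cm_rf")) {
    imp <- data.table(feature = x$feature_names, importance = x$importance)
  } else if (inherits(x, "cm_eval_report")) {
    if (is.null(x$importance)) stop("report lacks importances; rerun with keep_importance = TRUE")
    imp <- copy(x$importance)
  } else stop("x must be a cm_rf or cm_eval_report")
  matrix <- as.data.table(matrix)
  stopifnot("ams" %in% names(matrix))

  r <- vapply(imp$feature, function(f) {
    v <- matrix[[f]]
    ok <- !is.na(v) & !is.na(matrix$ams)
    if (sum(ok) < 3 || sd(v[ok]) == 0 || sd(matrix$ams[ok]) == 0) return(NA_real_)
    cor(v[ok], matrix$ams[ok])
  }, numeric(1))
  imp[, pearson_r := r]

  if (aggregate) {
    imp[, feature := sub("_(3|6|12)d_(mean|stdev|gradient)$", "", feature)]
    agg <- imp[, .(importance = sum(importance),
                   sd = if ("sd" %in% names(imp)) sqrt(sum(sd^2)) else NA_real_),
               by = feature]
    # direction of a family from the basic (daily) feature's correlation
    base_r <- r[match(agg$feature, names(r))]
    agg[, pearson_r := base_r]
    imp <- agg
  }
  tot <- sum(imp$importance)
  if (tot > 0) imp[, importance := importance / tot]
  imp[, direction := fifelse(is.na(pearson_r) | abs(pearson_r) < 0.1, "undirected",
                             fifelse(pearson_r > 0, "positive", "negative"))]
  setorder(imp, -importance)
  imp[]
}

# ---- ablation -------------------------------------------------------------

#' Ablate feature families
#'
#' Re-runs the rolling evaluation with one or more of the four feature
#' families (steps, light, sleep, heart-rate) removed — each family takes
#' its basic features and all their window statistics with it — and
#' reports the AUC change relative to the full model.
#'
#' @param matrix,scheme,label,rf As in [rolling_evaluate()].
#' @param family Character vector among
#'   `r paste(names(FEATURE_FAMILIES), collapse = ", ")`.
#' @param baseline Optional full-model `cm_eval_report` to compare against
#'   (computed here if omitted).
#' @return List of class `cm_ablation`: `report` (partial model),
#'   `baseline`, `removed` (columns dropped), `auc_delta`
#'   (partial - full).
#' @export
ablate_family <- function(matrix, family, scheme, label = label_spec(),
                          rf = list(ntree = 500, seed = 1), baseline = NULL) {
  unknown <- setdiff(family, names(FEATURE_FAMILIES))
  if (length(unknown)) {
    stop("unknown feature family(ies): ", paste(unknown, collapse = ", "),
         " (expected ", paste(names(FEATURE_FAMILIES), collapse = "/"), ")")
  }
  all_cols <- feature_names()
  removed <- all_cols[family_of_column(all_cols) %in% family]
  kept <- setdiff(all_cols, removed)
  if (!length(kept)) stop("ablating all families leaves no predictors")
  if (is.null(baseline)) {
    baseline <- rolling_evaluate(matrix, scheme, label, rf)
  }
  rep <- rolling_evaluate(matrix, scheme, label, rf, features = kept)
  structure(list(report = rep, baseline = baseline, removed = removed,
                 family = family,
                 auc_delta = rep$summary$auc[["mean"]] - baseline$summary$auc[["mean"]]),
            class = "cm_ablation")
}

#' @export
print.cm_ablation <- function(x, ...) {
  cat(sprintf("<cm_ablation> without %s: %d columns removed, AUC %.3f (full %.3f, delta %+.3f)\n",
              paste(x$family, collapse = "+"), length(x$removed),
              x$report$summary$auc[["mean"]], x$baseline$summary$auc[["mean"]],
              x$auc_delta))
  invisible(x)
}

# ---- general vs personalized ----------------------------------------------

#' Compare a general model against personalized models
#'
#' For each patient, the personalized model is the usual rolling-origin
#' evaluation on that patient's own rows; the general model is a single
#' forest trained on all other patients' complete labeled rows and scored
#' on the same test windows. Reports per-patient mean accuracies, the
#' fraction of patients where the personalized model wins, and the mean
#' accuracy advantage.
#'
#' @param matrix Pooled labeled matrix with `patient_id`.
#' @param scheme,label,rf As in [rolling_evaluate()].
#' @return List of class `cm_comparison`: `per_patient` (`data.table`),
#'   `pct_personalized_wins`, `mean_advantage`, `n_skipped_patients`.
#' @export
compare_general_personalized <- function(matrix, scheme, label = label_spec(),
                                         rf = list(ntree = 500, seed = 1)) {
  matrix <- as.data.table(matrix)
  pids <- unique(matrix$patient_id)
  if (length(pids) < 2) stop("general model undefined with a single patient")
  feats <- feature_names()

  rows_all <- prepare_model_rows(matrix, label, feats)
  out <- list(); skipped <- 0L
  for (pid in pids) {
    own <- rows_all[patient_id == pid]
    others <- rows_all[patient_id != pid]
    pers <- tryCatch(rolling_evaluate(own, scheme, label, rf),
                     error = function(e) NULL)
    if (is.null(pers) || !nrow(others)) {
      skipped <- skipped + 1L
      message("compare_general_personalized: skipping patient ", pid,
              " (too few rows for a rolling evaluation)")
      next
    }
    # one general forest on everyone else
    if (label$type == "mood_state") {
      thr <- upper_tail_threshold(others$fwd3_ams, label$cutoff)
      y_g <- factor(fifelse(others$fwd3_ams >= thr, "biased", "neutral"),
                    levels = c("neutral", "biased"))
      positive <- "biased"
    } else {
      y_g <- factor(as.character(others$episode), levels = EPISODE_STATES)
      positive <- label$target
    }
    if (length(unique(as.character(y_g))) < 2L) {
      skipped <- skipped + 1L
      message("compare_general_personalized: skipping patient ", pid,
              " (single-class general training set)")
      next
    }
    gfit <- cm_rf(others[, ..feats], y_g, ntree = rf$ntree %||% 500,
                  mtry = rf$mtry, seed = round_seed(rf$seed %||% 1, 0L))
    gen_acc <- vapply(seq_len(nrow(pers$rounds)), function(i) {
      te <- own[date >= pers$rounds$test_min[i] & date <= pers$rounds$test_max[i]]
      if (label$type == "mood_state") {
        y_te <- fifelse(te$fwd3_ams >= thr, "biased", "neutral")
      } else {
        y_te <- as.character(te$episode)
      }
      pr <- predict(gfit, te[, ..feats], type = "prob")
      pred <- colnames(pr)[max.col(pr, ties.method = "first")]
      mean(pred == y_te)
    }, numeric(1))
    out[[length(out) + 1L]] <- data.table(
      patient_id = pid, n_rounds = pers$n_rounds,
      acc_personalized = pers$summary$accuracy[["mean"]],
      acc_general = mean(gen_acc))
  }
  if (!length(out)) stop("no patient admitted a comparison")
  per_patient <- rbindlist(out)
  per_patient[, advantage := acc_personalized - acc_general]
  structure(list(per_patient = per_patient,
                 pct_personalized_wins = 100 * mean(per_patient$advantage > 0),
                 mean_advantage = mean(per_patient$advantage),
                 n_skipped_patients = skipped),
            class = "cm_comparison")
}

#' @export
print.cm_comparison <- function(x, ...) {
  cat(sprintf("<cm_comparison> %d patients: personalized wins %.0f%%, mean advantage %+.3f\n",
              nrow(x$per_patient), x$pct_personalized_wins, x$mean_advantage))
  invisible(x)
}

utils::globalVariables(c("advantage", "acc_personalized", "acc_general",
                         "pearson_r", "importance", "feature", "complete"))
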