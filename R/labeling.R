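# Mood labels.
#
# Two label schemes hang off the daily self-rated mood score (-3..+3):
#   * mood state (2-class): the absolute mood score AMS = |score| (0..3,
#     higher = more unstable in either direction) is averaged over the
#     following 3 days; days in the top cutoff% of that forward mean are
#     "biased", the rest "neutral".
#   * episode (4-class): clinician intervals label each day DE/ME/HME,
#     with NE (euthymic) outside all intervals.

#' Absolute mood score
#'
#' `AMS = |score|`: folds the bipolar -3..+3 scale onto 0..3 so that
#' depressive and manic deviations both count as instability.
#' @param score Integer vector in -3..3.
#' @return Integer vector in 0..3.
#' @export
compute_ams <- function(score) {
  if (any(!is.na(score) & (score != round(score) | abs(score) > 3))) {
    stop("mood scores must be integers in [-3, 3]")
  }
  as.integer(abs(score))
}

# Upper-tail threshold as an order statistic: the top cutoff% of n values
# are the n - floor(n*(1-cutoff/100)) largest, so the threshold is
# x(k) with k = floor(n*(1-cutoff/100)) + 1 and "biased" means >= x(k)
# (ties at the threshold inflate the biased class). Pinned so the
# sort-based oracle comparison is exact.
upper_tail_threshold <- function(reference, cutoff_pct) {
  reference <- reference[!is.na(reference)]
  if (!length(reference)) stop("empty reference distribution")
  s <- sort(reference)
  k <- min(length(s), floor(length(s) * (1 - cutoff_pct / 100)) + 1L)
  s[k]
}

#' Attach AMS and the forward 3-day mean AMS
#'
#' `fwd3_ams` for day d is the mean AMS of days d+1..d+3, present only
#' when all three following days' scores exist (per patient, calendar
#' days).
#'
#' @param matrix `data.table` with `patient_id`, `date`, `mood_score`.
#' @return The matrix with `ams` and `fwd3_ams` columns added.
#' @export
add_forward_ams <- function(matrix) {
  matrix <- as.data.table(matrix)
  stopifnot(all(c("patient_id", "date", "mood_score") %in% names(matrix)))
  matrix[, ams := compute_ams(mood_score)]
  lk <- matrix[, .(patient_id, date, ams)]
  f <- lapply(1:3, function(k) {
    lk[matrix[, .(patient_id, date = date + k)], on = c("patient_id", "date"), x.ams]
  })
  matrix[, fwd3_ams := (f[[1]] + f[[2]] + f[[3]]) / 3]
  matrix[]
}

#' Two-class mood-state labels at a percentile cutoff
#'
#' Days whose forward 3-day mean AMS reaches the upper `cutoff_pct` tail of
#' the reference distribution are labeled `biased`; the rest `neutral`.
#' Ties at the threshold go to `biased`. Rows without `fwd3_ams` get `NA`
#' labels (excluded from modeling).
#'
#' @param matrix Output of [add_forward_ams()] (must carry `fwd3_ams`).
#' @param cutoff_pct Upper-tail percentage; 10, 30 and 50 are the standard
#'   settings (other values are allowed with a warning).
#' @param reference Numeric vector defining the threshold distribution;
#'   defaults to the matrix's own `fwd3_ams`. During rolling evaluation the
#'   training window's values are passed here to avoid test leakage.
#' @return The matrix with a `mood_state` factor (`neutral`/`biased`).
#' @export
label_mood_state <- function(matrix, cutoff_pct = 50, reference = NULL) {
  matrix <- as.data.table(matrix)
  stopifnot("fwd3_ams" %in% names(matrix))
  if (!cutoff_pct %in% c(10, 30, 50)) {
    warning("cutoff_pct ", cutoff_pct, " outside the standard {10, 30, 50} settings")
  }
  if (is.null(reference)) reference <- matrix$fwd3_ams
  thr <- upper_tail_threshold(reference, cutoff_pct)
  ref <- reference[!is.na(reference)]
  if (length(unique(ref)) == 1L) {
    warning("degenerate reference: all fwd3_ams equal; every labeled row is 'biased'")
  }
  matrix[, mood_state := factor(fifelse(fwd3_ams >= thr, "biased", "neutral"),
                                levels = c("neutral", "biased"))]
  setattr(matrix, "mood_state_threshold", thr)
  matrix[]
}

#' Episode label of given days
#'
#' @param dates `Date` vector.
#' @param episodes `data.table(start, end, type)` with inclusive interval
#'   ends and types among DE/ME/HME; intervals must not overlap.
#' @return Factor with levels NE/DE/ME/HME; NE outside all intervals.
#' @export
label_episode <- function(dates, episodes) {
  dates <- as.Date(dates)
  lab <- rep("NE", length(dates))
  if (!is.null(episodes) && nrow(episodes)) {
    episodes <- as.data.table(episodes)
    bad <- setdiff(unique(episodes$type), c("DE", "ME", "HME"))
    if (length(bad)) stop("unknown episode type(s): ", paste(bad, collapse = ", "))
    ep <- episodes[order(start)]
    if (nrow(ep) > 1 && any(ep$start[-1] <= ep$end[-nrow(ep)])) {
      stop("validation error: overlapping episode intervals")
    }
    for (i in seq_len(nrow(ep))) {
      lab[dates >= ep$start[i] & dates <= ep$end[i]] <- ep$type[i]
    }
  }
  factor(lab, levels = EPISODE_STATES)
}

#' Join features with mood scores and labels
#'
#' Produces the modeling table: feature rows joined with the mood score,
#' AMS, forward 3-day AMS, episode label, and (optionally) a mood-state
#' label at a whole-matrix reference. Rolling evaluation recomputes
#' mood-state labels per training window instead; the column attached here
#' reproduces whole-data thresholding.
#'
#' @param features Output of [build_feature_matrix()].
#' @param bundles The bundle list the features came from (for mood scores
#'   and episode intervals).
#' @param cutoff_pct Optional mood-state cutoff; `NULL` skips the global
#'   `mood_state` column.
#' @return `data.table` with feature columns plus `mood_score`, `ams`,
#'   `fwd3_ams`, `episode` and optionally `mood_state`.
#' @export
build_labeled_matrix <- function(features, bundles, cutoff_pct = NULL) {
  if (inherits(bundles, "cm_bundle")) bundles <- list(bundles)
  features <- as.data.table(features)
  moods <- rbindlist(lapply(bundles, function(b)
    data.table(patient_id = b$patient_id, date = as.Date(b$mood$date),
               mood_score = b$mood$score)))
  out <- moods[features, on = c("patient_id", "date")]
  out <- add_forward_ams(out)
  eps <- lapply(bundles, function(b) b$episodes)
  names(eps) <- vapply(bundles, function(b) b$patient_id, character(1))
  out[, episode := label_episode(date, eps[[patient_id[1]]]), by = patient_id]
  if (!is.null(cutoff_pct)) out <- label_mood_state(out, cutoff_pct)
  setcolorder(out, c("patient_id", "date", feature_names()))
  out[]
}
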