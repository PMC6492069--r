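# Daily circadian features.
#
# 13 basic features per patient-day, four families:
#   steps:      steps_during_bedtime, steps_during_daytime
#   light:      light_exposure_during_bedtime, light_exposure_during_daytime
#   sleep:      sleep_length, sleep_efficiency, sleep_onset_dev, sleep_offset_dev
#   heart-rate: HR_CR_amplitude, HR_CR_acrophase, HR_CR_mesor, HR_CR_rsquared,
#               resting_heart_rate
# plus 13 x {3,6,12}-day x {mean, stdev, gradient} trailing-window
# statistics = 130 columns.
#
# Anti-leakage convention: every quantity attributed to day d is computable
# at the end of day d. The bedtime slot of day d's features is therefore
# the night ENDING at sunrise(d) (the night whose sleep record is also
# attributed to day d), and the 48-h cosinor window covers days d-1 and d.

BASIC_FEATURES <- c(
  "steps_during_bedtime", "steps_during_daytime",
  "light_exposure_during_bedtime", "light_exposure_during_daytime",
  "sleep_length", "sleep_efficiency", "sleep_onset_dev", "sleep_offset_dev",
  "HR_CR_amplitude", "HR_CR_acrophase", "HR_CR_mesor", "HR_CR_rsquared",
  "resting_heart_rate"
)
EXT_WINDOWS <- c(3L, 6L, 12L)
EXT_STATS <- c("mean", "stdev", "gradient")

#' Names of the 130 feature columns, in canonical order
#'
#' The 13 basic features followed by `<basic>_<w>d_<stat>` for each basic
#' feature, window w in 3/6/12 days and statistic mean/stdev/gradient.
#' @return Character vector of length 130.
#' @export
feature_names <- function() {
  ext <- as.vector(vapply(BASIC_FEATURES, function(b)
    as.vector(outer(EXT_WINDOWS, EXT_STATS,
                    function(w, s) paste0(b, "_", w, "d_", s))),
    character(length(EXT_WINDOWS) * length(EXT_STATS))))
  c(BASIC_FEATURES, ext)
}

# ---- circular helpers (24-h clock) ----------------------------------------

circ_mean_hours <- function(h) {
  a <- h * 2 * pi / 24
  (atan2(mean(sin(a)), mean(cos(a))) * 24 / (2 * pi)) %% 24
}

# signed shortest difference a - b on the 24-h circle, in (-12, 12]
circ_diff_hours <- function(a, b) {
  d <- (a - b) %% 24
  ifelse(d > 12, d - 24, d)
}

# clock hour of a local-face timestamp
clock_hours <- function(ts, site) {
  (as.numeric(ts) %% 86400) / 3600
}

#' Sleep-timing regularity: deviation from the trailing circular mean
#'
#' Measures how far today's sleep onset (or offset) clock time sits from
#' the circular mean of the preceding week's clock times, on the 24-hour
#' circle, so a 23:00-vs-01:00 discrepancy counts as 2 h, never 22 h.
#' Missing when day `d` has no record or fewer than `min_records` of the 7
#' preceding days do.
#'
#' @param sleep `data.table(date, onset, offset, ...)` for one patient.
#' @param d Date of interest.
#' @param which `"onset"` or `"offset"`.
#' @param site A [cm_site()] (for clock-time extraction).
#' @param window Trailing history length in days (default 7).
#' @param min_records Minimum history records required (default 3).
#' @return Absolute deviation in hours (`[0, 12]`), or `NA`.
#' @export
sleep_timing_dev <- function(sleep, d, which = c("onset", "offset"), site,
                             window = 7, min_records = 3) {
  which <- match.arg(which)
  d <- as.Date(d)
  today <- sleep[date == d]
  if (nrow(today) != 1) return(NA_real_)
  hist <- sleep[date >= d - window & date <= d - 1]
  if (nrow(hist) < min_records) return(NA_real_)
  th <- clock_hours(today[[which]], site)
  hh <- clock_hours(hist[[which]], site)
  abs(circ_diff_hours(th, circ_mean_hours(hh)))
}

# ---- basic features -------------------------------------------------------

# Sum (steps) or mean (lux) of a timestamped stream inside the bedtime and
# daytime slots of each date. A mean over an empty slot is NA; a sum over
# an empty slot is 0 when the stream was recorded on a civil day the slot
# overlaps (the tracker was worn, it just saw no events) and NA when the
# stream is absent for all overlapping days (day-granular missingness).
window_stat <- function(dt, value_col, dates, solar, site, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  out <- data.table(date = dates, bed = NA_real_, day = NA_real_)
  if (!nrow(dt)) return(out)
  v <- dt[[value_col]]
  ts <- dt$timestamp
  cd <- local_civil_date(ts, site)
  ch <- clock_hours(ts, site)

  sr <- solar$sunrise_h[match(cd, solar$date)]
  ss <- solar$sunset_h[match(cd, solar$date)]
  # bedtime slot attributed to day D = night ending at sunrise(D):
  # a sample belongs to night D = its date if before that date's sunrise,
  # else night D = date + 1 (evening tail of the 8-h block).
  night <- fifelse(ch < sr, cd, cd + 1L)
  sr_n <- solar$sunrise_h[match(night, solar$date)]
  # membership in [sunrise(D) - 8h, sunrise(D)): evening part has clock
  # >= sunrise(D) - 8 + 24 on day D-1; morning part clock < sunrise(D).
  in_bed <- !is.na(sr_n) &
    fifelse(night == cd, ch < sr_n & ch >= sr_n - 8,
            ch >= sr_n - 8 + 24)
  in_day <- !is.na(sr) & ch >= sr & ch < ss

  agg <- function(mask, key) {
    if (!any(mask)) return(NULL)
    g <- data.table(k = key[mask], v = v[mask])
    if (stat == "sum") g[, .(val = sum(v)), by = k] else g[, .(val = mean(v)), by = k]
  }
  if (stat == "sum") {
    present <- unique(cd)
    set(out, i = which(dates %in% present | (dates - 1L) %in% present),
        j = "bed", value = 0)
    set(out, i = which(dates %in% present), j = "day", value = 0)
  }
  bed_agg <- agg(in_bed, night)
  day_agg <- agg(in_day, cd)
  if (!is.null(bed_agg)) set(out, i = match(bed_agg$k, dates), j = "bed", value = bed_agg$val)
  if (!is.null(day_agg)) set(out, i = match(day_agg$k, dates), j = "day", value = day_agg$val)
  out
}

#' Compute the 13 basic features for every day of a bundle
#'
#' @param bundle A `cm_bundle`.
#' @param dates Optional `Date` vector; defaults to the full span covered
#'   by any stream.
#' @param min_cosinor_samples Minimum HR samples in the 48-h window for a
#'   valid cosinor fit (default 1440 = 50% of the expected minute grid).
#' @return `data.table(date, <13 basic features>)`, one row per day, with
#'   `NA` wherever the inputs are absent.
#' @export
daily_basic_features <- function(bundle, dates = NULL,
                                 min_cosinor_samples = 1440) {
  stopifnot(inherits(bundle, "cm_bundle"))
  site <- bundle$site
  if (is.null(dates)) {
    cand <- c(
      if (nrow(bundle$hr)) range(local_civil_date(bundle$hr$timestamp, site)),
      if (nrow(bundle$steps)) range(local_civil_date(bundle$steps$timestamp, site)),
      if (nrow(bundle$light)) range(local_civil_date(bundle$light$timestamp, site)),
      if (nrow(bundle$sleep)) range(as.Date(bundle$sleep$date)),
      if (nrow(bundle$mood)) range(as.Date(bundle$mood$date)))
    if (!length(cand)) stop("bundle has no data")
    dates <- seq(min(as.Date(cand, origin = "1970-01-01")),
                 max(as.Date(cand, origin = "1970-01-01")), by = "day")
  }
  dates <- as.Date(dates)
  solar <- sun_times(seq(min(dates) - 1L, max(dates) + 1L, by = "day"), site)

  out <- data.table(date = dates)
  st <- window_stat(bundle$steps, "steps", dates, solar, site, "sum")
  out[, `:=`(steps_during_bedtime = st$bed, steps_during_daytime = st$day)]
  li <- window_stat(bundle$light, "lux", dates, solar, site, "mean")
  out[, `:=`(light_exposure_during_bedtime = li$bed,
             light_exposure_during_daytime = li$day)]

  sl <- bundle$sleep
  ix <- match(dates, as.Date(sl$date))
  out[, sleep_length := as.numeric(sl$offset[ix] - sl$onset[ix], units = "hours")]
  out[, sleep_efficiency := sl$efficiency[ix]]
  out[, sleep_onset_dev := vapply(dates, function(d)
    sleep_timing_dev(sl, d, "onset", site), numeric(1))]
  out[, sleep_offset_dev := vapply(dates, function(d)
    sleep_timing_dev(sl, d, "offset", site), numeric(1))]

  # heart rate: 48-h cosinor ending with day d, plus resting HR of day d
  hr <- bundle$hr
  amp <- acr <- mes <- rsq <- rest <- rep(NA_real_, length(dates))
  if (nrow(hr)) {
    hr_date <- local_civil_date(hr$timestamp, site)
    hr_sec <- as.numeric(hr$timestamp)
    by_day <- split(seq_len(nrow(hr)), hr_date)
    midn_sec <- as.numeric(local_midnight(dates, site))
    for (i in seq_along(dates)) {
      idx <- c(by_day[[as.character(dates[i] - 1L)]],
               by_day[[as.character(dates[i])]])
      if (length(idx) >= min_cosinor_samples) {
        t_h <- (hr_sec[idx] - (midn_sec[i] - 86400)) / 3600
        f <- fit_cosinor(t_h, hr$bpm[idx], min_samples = min_cosinor_samples)
        amp[i] <- f$amplitude; acr[i] <- f$acrophase
        mes[i] <- f$mesor; rsq[i] <- f$r_squared
      }
      di <- by_day[[as.character(dates[i])]]
      if (length(di) >= 5) {
        roll <- frollmean(hr$bpm[di], 5)
        rest[i] <- min(roll, na.rm = TRUE)
      }
    }
  }
  out[, `:=`(HR_CR_amplitude = amp, HR_CR_acrophase = acr,
             HR_CR_mesor = mes, HR_CR_rsquared = rsq,
             resting_heart_rate = rest)]
  out[]
}

#' Basic features of a single patient-day
#'
#' Convenience wrapper around [daily_basic_features()]; history days are
#' still consulted for the regularity and cosinor fields.
#' @inheritParams daily_basic_features
#' @param d Date of interest.
#' @return One-row `data.table`.
#' @export
basic_features <- function(bundle, d, min_cosinor_samples = 1440) {
  d <- as.Date(d)
  span <- seq(d - 8L, d, by = "day")
  daily_basic_features(bundle, dates = span,
                       min_cosinor_samples = min_cosinor_samples)[date == d]
}

# ---- extended features ----------------------------------------------------

roll_stat <- function(x, w, stat) {
  n <- length(x)
  if (stat == "mean") return(frollmean(x, w, na.rm = FALSE))
  xc <- seq_len(w) - (w + 1) / 2
  denom <- sum(xc^2)
  frollapply(x, w, function(v) {
    if (anyNA(v)) return(NA_real_)
    if (stat == "stdev") sd(v) else sum(xc * v) / denom
  })
}

# shortest-arc unwrapping of an acrophase series so that windowed
# statistics do not see 0/24 wrap jumps
unwrap_hours <- function(a) {
  u <- a
  ref <- NA_real_
  for (i in seq_along(a)) {
    if (is.na(a[i])) next
    if (is.na(ref)) u[i] <- a[i] else u[i] <- ref + circ_diff_hours(a[i], ref %% 24)
    ref <- u[i]
  }
  u
}

#' Expand daily basic features into the 130-column feature row
#'
#' For every basic feature and trailing window w in {3, 6, 12} days
#' (covering days d-w+1..d inclusive), appends the window mean, sample SD
#' (denominator w-1) and OLS gradient of value against day index (units:
#' per day). A window statistic is missing whenever any constituent day is.
#' Acrophase series are unwrapped along the shortest arc first, and the
#' windowed acrophase mean is reported modulo 24.
#'
#' @param basic `data.table(date, <13 basic features>)`, one row per
#'   consecutive day (gaps are filled with missing rows first).
#' @return `data.table(date, <130 features>, complete)`.
#' @export
extend_features <- function(basic) {
  basic <- as.data.table(basic)
  stopifnot("date" %in% names(basic), all(BASIC_FEATURES %in% names(basic)))
  # ensure a contiguous daily grid so "past w days" means calendar days
  grid <- data.table(date = seq(min(basic$date), max(basic$date), by = "day"))
  out <- basic[grid, on = "date"]

  for (b in BASIC_FEATURES) {
    x <- out[[b]]
    xs <- if (b == "HR_CR_acrophase") unwrap_hours(x) else x
    for (w in EXT_WINDOWS) {
      for (s in EXT_STATS) {
        v <- roll_stat(xs, w, s)
        if (b == "HR_CR_acrophase" && s == "mean") v <- v %% 24
        set(out, j = paste0(b, "_", w, "d_", s), value = v)
      }
    }
  }
  setcolorder(out, c("date", feature_names()))
  out[, complete := rowSums(is.na(.SD)) == 0L, .SDcols = feature_names()]
  out[]
}

#' Build the feature matrix for one or more patients
#'
#' Runs [daily_basic_features()] and [extend_features()] per bundle and
#' stacks the results with patient ids.
#'
#' @param bundles A `cm_bundle` or (named) list of them.
#' @param min_cosinor_samples Passed to [daily_basic_features()].
#' @return `data.table(patient_id, date, <130 features>, complete)`.
#' @export
build_feature_matrix <- function(bundles, min_cosinor_samples = 1440) {
  if (inherits(bundles, "cm_bundle")) bundles <- list(bundles)
  rbindlist(lapply(bundles, function(b) {
    basic <- daily_basic_features(b, min_cosinor_samples = min_cosinor_samples)
    ext <- extend_features(basic)
    cbind(data.table(patient_id = b$patient_id), ext)
  }))
}
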