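# File formats and validation.
#
# Cohort directory layout (all plain CSV, timestamps ISO-8601 with explicit
# UTC offset):
#   hr.csv       patient_id,timestamp,bpm
#   steps.csv    patient_id,timestamp,steps
#   light.csv    patient_id,timestamp,lux
#   sleep.csv    patient_id,date,onset,offset,efficiency
#   mood.csv     patient_id,date,score
#   episodes.csv patient_id,start,end,type
#   site.yaml    latitude, longitude, tz, optional suntimes: path to
#                suntimes.csv (date,sunrise,sunset) overriding solar times

# ISO-8601 with explicit offset, handled textually: timestamps are held
# internally as local-civil-time faces (see solar.R), so formatting
# appends the site's offset and parsing re-bases any foreign offset onto
# the site's. No tz-database conversion is involved.
format_iso_ts <- function(ts, site) {
  sprintf("%s%+03d:00", format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
          site$tz_offset)
}

parse_iso_ts <- function(x, site) {
  m <- regmatches(x, regexec(
    "^(\\d{4}-\\d{2}-\\d{2})[T ](\\d{2}:\\d{2}:\\d{2})(Z|[+-]\\d{2}:?\\d{2})?$",
    as.character(x)))
  face <- rep(NA_real_, length(x))
  off <- rep(site$tz_offset, length(x))
  ok <- lengths(m) == 4
  if (any(ok)) {
    parts <- m[ok]
    dt <- vapply(parts, function(p) paste(p[2], p[3]), character(1))
    face[ok] <- as.numeric(as.POSIXct(dt, format = "%Y-%m-%d %H:%M:%S",
                                      tz = "UTC"))
    ostr <- vapply(parts, function(p) p[4], character(1))
    has_off <- ostr != "" & !is.na(ostr)
    oh <- numeric(sum(ok))
    oh[] <- site$tz_offset
    if (any(has_off)) {
      z <- ostr[has_off]
      zc <- gsub(":", "", z) # "+0900", "-0430" or "Z"
      neg <- substr(zc, 1, 1) == "-"
      hh <- suppressWarnings(as.numeric(substr(zc, 2, 3)))
      mm <- suppressWarnings(as.numeric(substr(zc, 4, 5))) / 60
      mag <- ifelse(is.na(hh), 0, hh) + ifelse(is.na(mm), 0, mm)
      oh[has_off] <- ifelse(z == "Z", 0, ifelse(neg, -mag, mag))
    }
    off[ok] <- oh
  }
  # re-base a foreign offset onto the site's local face
  .POSIXct(face + (site$tz_offset - off) * 3600, tz = "UTC")
}

#' Construct a per-patient sensor bundle
#'
#' The in-memory container for one patient's raw streams: minute heart
#' rate, minute steps, light samples, nightly sleep records, daily mood
#' scores, clinician episode intervals, and the observation site.
#'
#' @param patient_id Character id.
#' @param hr `data.table(timestamp, bpm)`.
#' @param steps `data.table(timestamp, steps)`.
#' @param light `data.table(timestamp, lux)`.
#' @param sleep `data.table(date, onset, offset, efficiency)`; a record is
#'   attributed to the calendar day containing its offset (wake-up date).
#' @param mood `data.table(date, score)`, score integer in -3..3.
#' @param episodes `data.table(patient_id, start, end, type)`, type in
#'   DE/ME/HME; days outside all intervals are NE.
#' @param site A [cm_site()].
#' @return Object of class `cm_bundle`.
#' @export
new_bundle <- function(patient_id, hr, steps, light, sleep, mood, episodes, site) {
  b <- list(patient_id = patient_id,
            hr = as.data.table(hr), steps = as.data.table(steps),
            light = as.data.table(light), sleep = as.data.table(sleep),
            mood = as.data.table(mood), episodes = as.data.table(episodes),
            site = site)
  class(b) <- "cm_bundle"
  b
}

#' @export
print.cm_bundle <- function(x, ...) {
  cat(sprintf("<cm_bundle> %s: %d HR, %d step, %d light samples; %d sleep, %d mood records; %d episodes\n",
              x$patient_id, nrow(x$hr), nrow(x$steps), nrow(x$light),
              nrow(x$sleep), nrow(x$mood), nrow(x$episodes)))
  invisible(x)
}

#' Write a cohort of bundles to a directory
#'
#' Emits the documented CSV schemas (one file per stream, all patients
#' concatenated) plus `site.yaml`. Output is byte-stable: rewriting the
#' same bundles produces identical files.
#'
#' @param bundles A `cm_bundle` or list of them.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundles, dir) {
  if (inherits(bundles, "cm_bundle")) bundles <- list(bundles)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  site <- bundles[[1]]$site

  gather <- function(stream, fmt) {
    rbindlist(lapply(bundles, function(b) {
      dt <- copy(b[[stream]])
      if (!nrow(dt)) return(fmt(dt, b))
      fmt(dt, b)
    }))
  }
  fwrite(gather("hr", function(dt, b)
    data.table(patient_id = rep(b$patient_id, nrow(dt)),
               timestamp = format_iso_ts(dt$timestamp, site), bpm = dt$bpm)),
    file.path(dir, "hr.csv"))
  fwrite(gather("steps", function(dt, b)
    data.table(patient_id = rep(b$patient_id, nrow(dt)),
               timestamp = format_iso_ts(dt$timestamp, site), steps = dt$steps)),
    file.path(dir, "steps.csv"))
  fwrite(gather("light", function(dt, b)
    data.table(patient_id = rep(b$patient_id, nrow(dt)),
               timestamp = format_iso_ts(dt$timestamp, site), lux = dt$lux)),
    file.path(dir, "light.csv"))
  fwrite(gather("sleep", function(dt, b)
    data.table(patient_id = rep(b$patient_id, nrow(dt)),
               date = as.character(dt$date),
               onset = format_iso_ts(dt$onset, site),
               offset = format_iso_ts(dt$offset, site),
               efficiency = dt$efficiency)),
    file.path(dir, "sleep.csv"))
  fwrite(gather("mood", function(dt, b)
    data.table(patient_id = rep(b$patient_id, nrow(dt)),
               date = as.character(dt$date), score = dt$score)),
    file.path(dir, "mood.csv"))
  fwrite(gather("episodes", function(dt, b)
    data.table(patient_id = rep(b$patient_id, nrow(dt)),
               start = as.character(dt$start), end = as.character(dt$end),
               type = dt$type)),
    file.path(dir, "episodes.csv"))

  site_y <- list(latitude = site$latitude, longitude = site$longitude,
                 tz = site$tz_offset)
  if (!is.null(site$suntimes)) {
    fwrite(site$suntimes, file.path(dir, "suntimes.csv"))
    site_y$suntimes <- "suntimes.csv"
  }
  yaml::write_yaml(site_y, file.path(dir, "site.yaml"))
  invisible(dir)
}

#' Read the site descriptor of a cohort directory
#' @param dir Cohort directory containing `site.yaml`.
#' @return A [cm_site()].
#' @export
read_site <- function(dir) {
  path <- file.path(dir, "site.yaml")
  if (!file.exists(path)) stop("missing site.yaml in ", dir)
  y <- yaml::read_yaml(path)
  for (k in c("latitude", "longitude", "tz")) {
    if (is.null(y[[k]])) stop("site.yaml missing required field: ", k)
  }
  suntimes <- NULL
  if (!is.null(y$suntimes)) {
    sp <- file.path(dir, y$suntimes)
    if (!file.exists(sp)) stop("suntimes table not found: ", sp)
    suntimes <- fread(sp)
  }
  cm_site(y$latitude, y$longitude, y$tz, suntimes = suntimes)
}

require_columns <- function(dt, cols, file) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stop(sprintf("format error in %s: missing required column(s): %s",
                 file, paste(miss, collapse = ", ")))
  }
}

check_monotone <- function(ts, pid, file) {
  if (length(ts) > 1 && any(diff(as.numeric(ts)) <= 0)) {
    stop(sprintf("validation error in %s: timestamps not strictly increasing for patient %s",
                 file, pid))
  }
}

#' Read a cohort directory into validated bundles
#'
#' Rows failing range rules (non-positive bpm, negative steps or lux,
#' non-integer or out-of-range mood scores, efficiency outside `[0,100]`,
#' sleep onset not before offset, unknown episode types, unparseable
#' timestamps) are rejected and counted, never silently dropped. Structural
#' problems — a missing required column, non-monotone timestamps within a
#' patient's stream — are errors.
#'
#' @param dir Directory with the documented CSV schemas (see
#'   [write_bundle()]); empty header-only files are allowed.
#' @param site Optional [cm_site()] overriding `site.yaml`.
#' @return Named list of `cm_bundle` with attribute `rejections`, a
#'   `data.table(file, reason, n)` of rejected-row counts.
#' @export
read_bundle <- function(dir, site = NULL) {
  if (is.null(site)) site <- read_site(dir)
  rej <- list()
  note <- function(file, reason, n) {
    if (n > 0) rej[[length(rej) + 1L]] <<- data.table(file = file, reason = reason, n = n)
  }

  read_ts_stream <- function(file, value_col, lower_ok) {
    dt <- fread(file.path(dir, file), colClasses = list(character = "timestamp"))
    require_columns(dt, c("patient_id", "timestamp", value_col), file)
    if (!nrow(dt)) {
      return(data.table(patient_id = character(), timestamp = as.POSIXct(character(), tz = site_tz(site)),
                        value = numeric())[, setnames(.SD, "value", value_col)])
    }
    ts <- parse_iso_ts(dt$timestamp, site)
    bad_ts <- is.na(ts)
    v <- suppressWarnings(as.numeric(dt[[value_col]]))
    bad_v <- is.na(v) | !lower_ok(v)
    note(file, "unparseable timestamp", sum(bad_ts))
    note(file, paste0("out-of-range ", value_col), sum(bad_v & !bad_ts))
    keep <- !bad_ts & !bad_v
    out <- data.table(patient_id = dt$patient_id[keep], timestamp = ts[keep], value = v[keep])
    setnames(out, "value", value_col)
    out
  }

  hr <- read_ts_stream("hr.csv", "bpm", function(v) v > 0)
  steps <- read_ts_stream("steps.csv", "steps", function(v) v >= 0)
  steps[, steps := as.integer(steps)] # counts
  light <- read_ts_stream("light.csv", "lux", function(v) v >= 0)

  sl <- fread(file.path(dir, "sleep.csv"),
              colClasses = list(character = c("date", "onset", "offset")))
  require_columns(sl, c("patient_id", "date", "onset", "offset", "efficiency"), "sleep.csv")
  if (nrow(sl)) {
    on <- parse_iso_ts(sl$onset, site); off <- parse_iso_ts(sl$offset, site)
    d <- as.Date(sl$date)
    eff <- suppressWarnings(as.numeric(sl$efficiency))
    bad <- is.na(on) | is.na(off) | is.na(d) | is.na(eff) | eff < 0 | eff > 100 | on >= off
    note("sleep.csv", "invalid sleep record", sum(bad))
    sleep <- data.table(patient_id = sl$patient_id[!bad], date = d[!bad],
                        onset = on[!bad], offset = off[!bad], efficiency = eff[!bad])
  } else {
    sleep <- data.table(patient_id = character(), date = as.Date(character()),
                        onset = as.POSIXct(character(), tz = site_tz(site)),
                        offset = as.POSIXct(character(), tz = site_tz(site)),
                        efficiency = numeric())
  }

  md <- fread(file.path(dir, "mood.csv"), colClasses = list(character = "date"))
  require_columns(md, c("patient_id", "date", "score"), "mood.csv")
  if (nrow(md)) {
    d <- as.Date(md$date)
    s <- suppressWarnings(as.numeric(md$score))
    bad <- is.na(d) | is.na(s) | s != round(s) | abs(s) > 3
    note("mood.csv", "out-of-range mood score", sum(bad))
    mood <- data.table(patient_id = md$patient_id[!bad], date = d[!bad],
                       score = as.integer(s[!bad]))
  } else {
    mood <- data.table(patient_id = character(), date = as.Date(character()),
                       score = integer())
  }

  ep <- fread(file.path(dir, "episodes.csv"),
              colClasses = list(character = c("start", "end", "type")))
  require_columns(ep, c("patient_id", "start", "end", "type"), "episodes.csv")
  if (nrow(ep)) {
    st <- as.Date(ep$start); en <- as.Date(ep$end)
    bad <- is.na(st) | is.na(en) | st > en | !(ep$type %in% c("DE", "ME", "HME"))
    note("episodes.csv", "invalid episode interval", sum(bad))
    episodes <- data.table(patient_id = ep$patient_id[!bad], start = st[!bad],
                           end = en[!bad], type = ep$type[!bad])
  } else {
    episodes <- data.table(patient_id = character(), start = as.Date(character()),
                           end = as.Date(character()), type = character())
  }

  pids <- sort(unique(c(hr$patient_id, steps$patient_id, light$patient_id,
                        sleep$patient_id, mood$patient_id, episodes$patient_id)))
  bundles <- lapply(pids, function(pid) {
    sub <- function(dt) dt[patient_id == pid, !"patient_id"]
    b_hr <- sub(hr); b_st <- sub(steps); b_li <- sub(light)
    check_monotone(b_hr$timestamp, pid, "hr.csv")
    check_monotone(b_st$timestamp, pid, "steps.csv")
    check_monotone(b_li$timestamp, pid, "light.csv")
    new_bundle(pid, b_hr, b_st, b_li, sub(sleep), sub(mood),
               episodes[patient_id == pid], site)
  })
  names(bundles) <- pids
  rejections <- if (length(rej)) rbindlist(rej) else
    data.table(file = character(), reason = character(), n = integer())
  if (nrow(rejections)) {
    message(sprintf("read_bundle: rejected %d row(s) across %d file(s)",
                    sum(rejections$n), length(unique(rejections$file))))
  }
  attr(bundles, "rejections") <- rejections
  bundles
}

# Feature-family assignment used for missingness accounting and ablation.
FEATURE_FAMILIES <- list(
  steps = c("steps_during_bedtime", "steps_during_daytime"),
  light = c("light_exposure_during_bedtime", "light_exposure_during_daytime"),
  sleep = c("sleep_length", "sleep_efficiency", "sleep_onset_dev", "sleep_offset_dev"),
  `heart-rate` = c("HR_CR_amplitude", "HR_CR_acrophase", "HR_CR_mesor",
                   "HR_CR_rsquared", "resting_heart_rate")
)

family_of_column <- function(cols) {
  base <- sub("_(3|6|12)d_(mean|stdev|gradient)$", "", cols)
  fam <- rep(NA_character_, length(cols))
  for (f in names(FEATURE_FAMILIES)) fam[base %in% FEATURE_FAMILIES[[f]]] <- f
  fam
}

#' Drop rows with any missing value among the 131 modeling columns
#'
#' A row survives only if all 130 features plus the mood score are present;
#' order is preserved and the filter is idempotent. The per-family share of
#' missing cells (steps / light / sleep / heart-rate / mood) is attached as
#' attribute `missingness` and reported via `message()`, mirroring the
#' pipeline's missing-data accounting.
#'
#' @param matrix A labeled feature matrix containing the 130 feature
#'   columns and `mood_score`.
#' @return The filtered matrix (possibly 0 rows), with attributes
#'   `missingness` (`data.table(family, n_missing, pct)`) and `n_dropped`.
#' @export
filter_complete_rows <- function(matrix) {
  matrix <- as.data.table(matrix)
  cols <- c(feature_names(), "mood_score")
  miss <- setdiff(cols, names(matrix))
  if (length(miss)) {
    stop("matrix lacks required column(s): ", paste(head(miss, 5), collapse = ", "))
  }
  na_mat <- is.na(as.matrix(matrix[, ..cols]))
  keep <- rowSums(na_mat) == 0L

  fam <- c(family_of_column(feature_names()), "mood")
  n_by_fam <- tapply(colSums(na_mat), fam, sum)
  tot <- sum(n_by_fam)
  missingness <- data.table(family = names(n_by_fam),
                            n_missing = as.integer(n_by_fam),
                            pct = if (tot > 0) 100 * as.numeric(n_by_fam) / tot else 0)
  out <- matrix[keep]
  setattr(out, "missingness", missingness)
  setattr(out, "n_dropped", sum(!keep))
  if (any(!keep)) {
    message(sprintf("filter_complete_rows: dropped %d of %d rows with missing values",
                    sum(!keep), length(keep)))
  }
  out
}
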