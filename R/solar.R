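# Sunrise/sunset and the sunrise-anchored timeslots.
#
# All light and activity features are computed inside two solar windows:
# "daytime" runs from sunrise to sunset of the same civil day, and
# "bedtime" is the fixed 8-hour block ending at the next sunrise, so the
# window start drifts with the seasons while its duration does not.

ZENITH_OFFICIAL <- 90.833 # degrees; includes refraction + solar radius

#' Describe an observation site
#'
#' A site carries the coordinates and fixed UTC offset used for solar
#' computations, plus an optional externally supplied sunrise/sunset table
#' that overrides the computed times verbatim.
#'
#' @param latitude Latitude in degrees, positive north. Polar latitudes
#'   (|latitude| >= 66) are refused: the timeslot definitions assume the sun
#'   rises and sets every day.
#' @param longitude Longitude in degrees, positive east.
#' @param tz_offset UTC offset of local civil time in whole hours.
#' @param suntimes Optional `data.frame` with columns `date`, `sunrise`,
#'   `sunset` (clock hours or ISO timestamps) overriding computed times.
#' @return An object of class `cm_site`.
#' @export
cm_site <- function(latitude, longitude, tz_offset = 0, suntimes = NULL) {
  stopifnot(is.numeric(latitude), is.numeric(longitude), is.numeric(tz_offset))
  if (abs(latitude) >= 66) {
    stop("unsupported site: |latitude| must be < 66 degrees (no polar day/night handling)")
  }
  if (!is.null(suntimes)) {
    suntimes <- as.data.table(suntimes)
    need <- c("date", "sunrise", "sunset")
    miss <- setdiff(need, names(suntimes))
    if (length(miss)) stop("suntimes table missing column(s): ", paste(miss, collapse = ", "))
    suntimes[, date := as.Date(date)]
  }
  structure(
    list(latitude = latitude, longitude = longitude,
         tz_offset = as.integer(round(tz_offset)), suntimes = suntimes),
    class = "cm_site"
  )
}

#' @export
print.cm_site <- function(x, ...) {
  cat(sprintf("<cm_site> lat %.4f, lon %.4f, UTC%+d%s\n", x$latitude,
              x$longitude, x$tz_offset,
              if (!is.null(x$suntimes)) sprintf(", %d override rows", nrow(x$suntimes)) else ""))
  invisible(x)
}

# Internal time representation: POSIXct carried in tz "UTC" whose clock
# face IS the site's local civil time (fixed offset, no DST). The UTC
# offset only exists at the file boundary (ISO-8601 suffix); named-zone
# conversion is deliberately never used, so behavior does not depend on
# the host's tz database.
site_tz <- function(site) "UTC"

#' Sunrise and sunset for a set of dates
#'
#' NOAA-style low-precision solar position: fractional year, equation of
#' time and solar declination from short Fourier series, hour angle at the
#' official zenith (90.833 deg). Accuracy is within a few minutes of
#' almanac values, well inside the +/- 5 minute contract. When the site
#' carries a `suntimes` override table, those values are returned verbatim
#' for the dates they cover.
#'
#' @param dates `Date` vector.
#' @param site A [cm_site()].
#' @return `data.table` with columns `date`, `sunrise`, `sunset`
#'   (POSIXct in the site's fixed-offset local time) and `sunrise_h`,
#'   `sunset_h` (local clock hours).
#' @export
sun_times <- function(dates, site) {
  stopifnot(inherits(site, "cm_site"))
  dates <- as.Date(dates)
  out <- data.table(date = dates)

  doy <- as.integer(strftime(dates, "%j", tz = "UTC"))
  gamma <- 2 * pi / 365 * (doy - 1 + 0.5) # evaluated at local solar noon
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) - 0.032077 * sin(gamma) -
                        0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  lat <- site$latitude * pi / 180
  cos_ha <- (cos(ZENITH_OFFICIAL * pi / 180) - sin(lat) * sin(decl)) /
    (cos(lat) * cos(decl))
  if (any(abs(cos_ha) > 1)) {
    stop("sun does not rise/set on some requested dates (polar condition)")
  }
  ha_deg <- acos(cos_ha) * 180 / pi
  # minutes after UTC midnight, then shift to local civil time
  sunrise_min <- 720 - 4 * (site$longitude + ha_deg) - eqtime + site$tz_offset * 60
  sunset_min  <- 720 - 4 * (site$longitude - ha_deg) - eqtime + site$tz_offset * 60
  out[, `:=`(sunrise_h = sunrise_min / 60, sunset_h = sunset_min / 60)]

  if (!is.null(site$suntimes)) {
    ov <- site$suntimes
    to_hours <- function(x, d) {
      if (is.numeric(x)) return(x)
      ts <- parse_iso_ts(as.character(x), site)
      as.numeric(ts - local_midnight(d, site), units = "hours")
    }
    idx <- match(out$date, ov$date)
    hit <- !is.na(idx)
    if (any(hit)) {
      out$sunrise_h[hit] <- to_hours(ov$sunrise[idx[hit]], ov$date[idx[hit]])
      out$sunset_h[hit]  <- to_hours(ov$sunset[idx[hit]], ov$date[idx[hit]])
    }
  }
  bad <- out$sunrise_h >= out$sunset_h
  if (any(bad)) stop("invalid solar times: sunrise must precede sunset")
  out[, `:=`(sunrise = local_midnight(date, site) + sunrise_h * 3600,
             sunset  = local_midnight(date, site) + sunset_h * 3600)]
  out[]
}

# POSIXct midnight (local-face) of a civil date.
local_midnight <- function(dates, site) {
  .POSIXct(as.numeric(as.Date(dates)) * 86400, tz = "UTC")
}

#' Bedtime timeslot of a day
#'
#' The bedtime slot attributed to day `d` is the half-open 8-hour interval
#' `[sunrise(d+1) - 8h, sunrise(d+1))`: the night that follows day `d`,
#' ending at the next sunrise. Its duration is exactly 8 hours on every
#' date; only its placement moves with the seasons.
#'
#' @param dates `Date` vector.
#' @param site A [cm_site()].
#' @param hours Window length in hours (default 8).
#' @return `data.table` with columns `date`, `start`, `end` (POSIXct,
#'   half-open `[start, end)`).
#' @export
bedtime_window <- function(dates, site, hours = 8) {
  dates <- as.Date(dates)
  st <- sun_times(dates + 1L, site)
  data.table(date = dates, start = st$sunrise - hours * 3600, end = st$sunrise)
}

#' Daytime timeslot of a day
#'
#' The half-open interval `[sunrise(d), sunset(d))` of the same civil day.
#'
#' @inheritParams bedtime_window
#' @return `data.table` with columns `date`, `start`, `end`.
#' @export
daytime_window <- function(dates, site) {
  dates <- as.Date(dates)
  st <- sun_times(dates, site)
  data.table(date = dates, start = st$sunrise, end = st$sunset)
}
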