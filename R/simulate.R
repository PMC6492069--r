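# Synthetic cohort generator.
#
# The generator stands in for a clinical cohort that is not publicly
# deposited. Its stated world: ~55 patients followed for up to two years at
# a mid-latitude site, each contributing minute-level heart rate and steps,
# irregular light samples, one nightly sleep record, one daily self-rated
# mood score (-3..+3), and clinician episode intervals. A latent per-day
# "instability" process (AR(1)-filtered function of a Markov episode state)
# drives both the mood score and — scaled by `coupling` — the circadian
# disruptions the downstream features are designed to detect: bedtime
# activity/light up, daytime activity/light down, sleep timing jitter up,
# heart-rate acrophase shifted.

#' Configuration for the synthetic cohort
#'
#' Defaults describe the emulated cohort: 55 patients, up to 730 days, a
#' Seoul-like site (UTC+9), a 70/10 bpm mesor/amplitude heart-rate rhythm
#' peaking mid-afternoon with 5 bpm noise, sleep 23:30--07:30 with 0.5 h
#' timing jitter, and a four-state daily episode process whose stationary
#' occupancy approximates the reported cohort mix (~82% no-episode, ~12%
#' depressive, ~1% manic, ~4% hypomanic).
#'
#' @param n_patients Number of patients.
#' @param n_days Days of follow-up per patient.
#' @param site A [cm_site()]; default Seoul coordinates, UTC+9.
#' @param start_date First civil day of follow-up.
#' @param hr_mesor,hr_amplitude,hr_acrophase,hr_noise_sd Heart-rate rhythm:
#'   mesor and amplitude in bpm, acrophase in clock hours, Gaussian noise SD
#'   in bpm.
#' @param sleep_onset,sleep_offset Baseline sleep onset/offset clock hours
#'   (onset belongs to the evening before the record's wake-up date).
#' @param sleep_jitter_sd SD (hours) of nightly timing jitter at zero
#'   disruption; jitter scales with `1 + coupling * instability`.
#' @param transition 4x4 daily transition matrix over states
#'   NE/DE/ME/HME (rows sum to 1).
#' @param polarity Named signs of the mood score per state (NE entries draw
#'   a random sign).
#' @param instability_base Named per-state mean of the latent instability.
#' @param instability_rho,instability_sd AR(1) memory and innovation SD of
#'   the instability process.
#' @param coupling Unitless >= 0: how strongly instability disrupts the
#'   sensor streams. 0 decouples mood from all sensors (null world).
#' @param missing_rates Named per-stream fractions in `[0,1]` of days whose
#'   stream is dropped entirely (names among hr/steps/light/sleep/mood).
#' @param day_noise_sd Log-scale SD of the day-level behavioral multiplier
#'   applied to activity and light (default 0.25): people vary far more
#'   day to day than the seasonal daylength drift, so calendar date is not
#'   finely readable from activity totals.
#' @param patient_hetero Scale in `[0, 1]` of between-patient trait
#'   offsets (mesor, acrophase, habitual sleep timing, activity level);
#'   1 = realistic heterogeneity, 0 = identical patients.
#' @param seed Integer master seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 55,
                       n_days = 730,
                       site = cm_site(37.5665, 126.9780, 9),
                       start_date = as.Date("2015-03-01"),
                       hr_mesor = 70, hr_amplitude = 10, hr_acrophase = 15,
                       hr_noise_sd = 5,
                       sleep_onset = 23.5, sleep_offset = 7.5,
                       sleep_jitter_sd = 0.5,
                       transition = default_transition(),
                       polarity = c(NE = 0, DE = -1, ME = 1, HME = 1),
                       instability_base = c(NE = 0.15, DE = 0.7, ME = 0.8, HME = 0.6),
                       instability_rho = 0.8, instability_sd = 0.25,
                       coupling = 1,
                       missing_rates = c(hr = 0, steps = 0, light = 0,
                                         sleep = 0, mood = 0),
                       day_noise_sd = 0.25,
                       patient_hetero = 1,
                       seed = 1) {
  cfg <- list(n_patients = as.integer(n_patients), n_days = as.integer(n_days),
              site = site, start_date = as.Date(start_date),
              hr_mesor = hr_mesor, hr_amplitude = hr_amplitude,
              hr_acrophase = hr_acrophase, hr_noise_sd = hr_noise_sd,
              sleep_onset = sleep_onset, sleep_offset = sleep_offset,
              sleep_jitter_sd = sleep_jitter_sd,
              transition = transition, polarity = polarity,
              instability_base = instability_base,
              instability_rho = instability_rho, instability_sd = instability_sd,
              coupling = coupling, missing_rates = missing_rates,
              day_noise_sd = day_noise_sd, patient_hetero = patient_hetero,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

EPISODE_STATES <- c("NE", "DE", "ME", "HME")

#' Default daily episode transition matrix
#'
#' Detailed-balance occupancy NE/DE/ME/HME = 82.3/12.3/1.0/4.1%, episode
#' durations of roughly a month, matching the emulated cohort's episode mix.
#' @return 4x4 row-stochastic matrix with dimnames NE/DE/ME/HME.
#' @export
default_transition <- function() {
  tm <- matrix(0, 4, 4, dimnames = list(EPISODE_STATES, EPISODE_STATES))
  tm["NE", ] <- c(1 - 0.0065, 0.0045, 0.0005, 0.0015)
  tm["DE", ] <- c(0.03, 0.97, 0, 0)
  tm["ME", ] <- c(0.04, 0, 0.96, 0)
  tm["HME", ] <- c(0.03, 0, 0, 0.97)
  tm
}

validate_sim_config <- function(cfg) {
  tm <- cfg$transition
  if (!is.matrix(tm) || !all(dim(tm) == c(4, 4)) ||
      any(tm < 0) || any(tm > 1) || any(abs(rowSums(tm) - 1) > 1e-8)) {
    stop("invalid transition matrix: must be 4x4 with entries in [0,1] and rows summing to 1")
  }
  if (cfg$hr_amplitude < 0) stop("hr_amplitude must be >= 0")
  if (cfg$coupling < 0) stop("coupling must be >= 0")
  if (any(cfg$missing_rates < 0 | cfg$missing_rates > 1)) {
    stop("missing_rates must lie in [0,1]")
  }
  if (cfg$n_patients < 1 || cfg$n_days < 1) stop("n_patients and n_days must be >= 1")
  invisible(cfg)
}

# Episode-state Markov chain, one state per day.
simulate_states <- function(n_days, transition) {
  states <- integer(n_days)
  states[1] <- 1L # start euthymic
  if (n_days > 1) {
    u <- runif(n_days - 1)
    cum <- t(apply(transition, 1, cumsum))
    for (d in 2:n_days) {
      states[d] <- findInterval(u[d - 1], cum[states[d - 1], ],
                                left.open = TRUE) + 1L
    }
  }
  states
}

# Latent instability: AR(1)-filtered per-state mean plus noise, clipped.
simulate_instability <- function(states, cfg) {
  base <- cfg$instability_base[EPISODE_STATES[states]]
  n <- length(states)
  eps <- rnorm(n, 0, cfg$instability_sd)
  inst <- numeric(n)
  inst[1] <- min(1, max(0, base[1] + eps[1]))
  rho <- cfg$instability_rho
  for (d in seq_len(n)[-1]) {
    inst[d] <- min(1, max(0, rho * inst[d - 1] + (1 - rho) * (base[d] + eps[d])))
  }
  inst
}

simulate_patient <- function(pid, cfg, solar) {
  n <- cfg$n_days
  dates <- cfg$start_date + seq_len(n) - 1L
  site <- cfg$site
  midn <- local_midnight(dates, site)

  # patient-level trait offsets (heterogeneity scale 0..1)
  h <- cfg$patient_hetero
  mesor_p <- cfg$hr_mesor + h * rnorm(1, 0, 3)
  acro_p <- cfg$hr_acrophase + h * rnorm(1, 0, 0.75)
  sleep_shift_p <- h * rnorm(1, 0, 0.75)
  act_p <- exp(h * rnorm(1, 0, 0.2))

  states <- simulate_states(n, cfg$transition)
  inst <- simulate_instability(states, cfg)
  delta <- cfg$coupling * inst          # per-day disruption magnitude
  ddelta <- pmin(1, delta)              # bounded form for multiplicative effects
  # day-level behavioral multipliers (mask the seasonal daylength trend)
  act_d <- exp(rnorm(n, 0, cfg$day_noise_sd))
  light_d <- exp(rnorm(n, 0, cfg$day_noise_sd))

  # --- heart rate: minute grid over the whole follow-up -------------------
  acro <- (acro_p + delta) %% 24
  tod <- rep((0:1439) / 60, n)                      # clock hours
  day_ix <- rep(seq_len(n), each = 1440)
  hr_val <- mesor_p +
    cfg$hr_amplitude * cos(2 * pi * (tod - acro[day_ix]) / 24)
  if (cfg$hr_noise_sd > 0) hr_val <- hr_val + rnorm(length(hr_val), 0, cfg$hr_noise_sd)
  hr_val <- pmax(hr_val, 25) # physiological floor keeps bpm > 0
  hr_ts <- rep(midn, each = 1440) + rep((0:1439) * 60, n)
  hr <- data.table(timestamp = hr_ts, bpm = hr_val) # full precision: noiseless fits must be exact

  # --- window membership for steps/light ----------------------------------
  # night d ends at sunrise(d); day d runs sunrise(d)..sunset(d)
  sunrise_h <- solar$sunrise_h[match(dates, solar$date)]
  sunset_h <- solar$sunset_h[match(dates, solar$date)]
  next_sunrise_h <- solar$sunrise_h[match(dates + 1L, solar$date)]
  in_bed <- (tod >= next_sunrise_h[day_ix] - 8 & tod < 24) |
    (tod < sunrise_h[day_ix]) # tail of last night's 8-h block
  in_day <- tod >= sunrise_h[day_ix] & tod < sunset_h[day_ix]

  # --- steps ---------------------------------------------------------------
  day_mult <- act_p * act_d
  lam <- numeric(length(tod))
  lam[in_day] <- 8 * day_mult[day_ix[in_day]] * (1 - 0.4 * ddelta[day_ix[in_day]])
  oth <- !in_day & !in_bed
  lam[oth] <- 4 * day_mult[day_ix[oth]]
  lam[in_bed] <- (0.05 + 3 * delta[day_ix[in_bed]]) * day_mult[day_ix[in_bed]]
  steps <- data.table(timestamp = hr_ts, steps = rpois(length(lam), lam))

  # --- light: one sample every 10 minutes ----------------------------------
  keep <- seq(1, length(tod), by = 10)
  lmean <- numeric(length(keep))
  lb <- in_bed[keep]; ld <- in_day[keep]; li <- day_ix[keep]
  lmean[ld] <- log(300 * light_d[li[ld]] * (1 - 0.4 * ddelta[li[ld]]))
  lmean[!ld & !lb] <- log(80 * light_d[li[!ld & !lb]])
  lmean[lb] <- log((0.5 + 20 * delta[li[lb]]) * light_d[li[lb]])
  lsd <- ifelse(lb, 0.8, 0.6)
  light <- data.table(timestamp = hr_ts[keep],
                      lux = round(rlnorm(length(keep), lmean, lsd), 3))

  # --- sleep: one record per wake-up date ----------------------------------
  jit_sd <- cfg$sleep_jitter_sd * (1 + delta)
  on_jit <- rnorm(n, 0, jit_sd)
  off_jit <- rnorm(n, 0, jit_sd)
  onset <- midn - 86400 + (cfg$sleep_onset + sleep_shift_p + on_jit) * 3600
  offset <- midn + (cfg$sleep_offset + sleep_shift_p + off_jit) * 3600
  short <- as.numeric(offset - onset, units = "hours") < 3
  onset[short] <- offset[short] - 3 * 3600 # floor: at least 3 h in bed
  effic <- pmin(100, pmax(50, 92 - 8 * ddelta + rnorm(n, 0, 2)))
  sleep <- data.table(date = dates, onset = onset, offset = offset,
                      efficiency = round(effic, 1))

  # --- mood ----------------------------------------------------------------
  pol <- cfg$polarity[EPISODE_STATES[states]]
  pol[pol == 0] <- sample(c(-1, 1), sum(pol == 0), replace = TRUE)
  score <- round(pol * (3 * inst) +
                   sample(c(-1L, 0L, 1L), n, replace = TRUE,
                          prob = c(0.15, 0.7, 0.15)))
  score <- pmin(3L, pmax(-3L, as.integer(score)))
  mood <- data.table(date = dates, score = score)

  # --- episode intervals from state runs -----------------------------------
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ep <- data.table(start = dates[starts], end = dates[ends],
                   type = EPISODE_STATES[r$values])[type != "NE"]

  truth <- data.table(patient_id = pid, date = dates, instability = inst,
                      episode_state = EPISODE_STATES[states],
                      true_mesor = mesor_p,
                      true_amplitude = cfg$hr_amplitude,
                      true_acrophase = acro)

  bundle <- new_bundle(pid, hr, steps, light, sleep, mood,
                       ep[, .(patient_id = pid, start, end, type)], site)
  list(bundle = bundle, truth = truth)
}

#' Simulate a synthetic cohort
#'
#' Generates one [SensorBundle][new_bundle] per patient plus a ground-truth
#' table of the latent quantities (instability, episode state, true daily
#' cosinor parameters). Reproducible: identical `(config, seed)` gives
#' identical output.
#'
#' @param config A [sim_config()].
#' @return List with `bundles` (list of `cm_bundle`, named by patient id)
#'   and `truth` (`data.table`: patient_id, date, instability,
#'   episode_state, true_mesor, true_amplitude, true_acrophase).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 1, n_days = 20, seed = 7))
#' cohort$bundles[[1]]
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  if (config$n_days < 13) {
    warning("n_days < 13: 12-day extended features can never be complete")
  }
  dates <- config$start_date + seq_len(config$n_days + 1L) - 1L
  solar <- sun_times(dates, config$site)
  bundles <- vector("list", config$n_patients)
  truth <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    set.seed((config$seed * 10007L + p) %% .Machine$integer.max)
    pid <- sprintf("P%03d", p)
    res <- simulate_patient(pid, config, solar)
    if (any(config$missing_rates > 0)) {
      res$bundle <- inject_missingness(
        res$bundle, config$missing_rates,
        seed = (config$seed * 20011L + p) %% .Machine$integer.max)
    }
    bundles[[p]] <- res$bundle
    truth[[p]] <- res$truth
  }
  names(bundles) <- vapply(bundles, function(b) b$patient_id, character(1))
  list(bundles = bundles, truth = rbindlist(truth))
}

#' Remove whole days of a stream, per stream
#'
#' Missingness is day-granular: with rate r, each calendar day's rows for
#' that stream are dropped independently with probability r (emulating a
#' tracker removed for a full day). Timestamped streams attribute a sample
#' to its civil date; sleep and mood use their record date.
#'
#' @param bundle A `cm_bundle`.
#' @param rates Named fractions in `[0,1]`, names among
#'   `hr, steps, light, sleep, mood`.
#' @param seed Integer seed.
#' @return The thinned bundle.
#' @export
inject_missingness <- function(bundle, rates, seed = 1) {
  stopifnot(inherits(bundle, "cm_bundle"))
  if (any(rates < 0 | rates > 1)) stop("missingness rates must lie in [0,1]")
  rates <- rates[rates > 0]
  if (!length(rates)) return(bundle)
  unknown <- setdiff(names(rates), c("hr", "steps", "light", "sleep", "mood"))
  if (length(unknown)) stop("unknown stream(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  site <- bundle$site
  for (stream in names(rates)) {
    dt <- bundle[[stream]]
    if (!nrow(dt)) next
    d <- if ("date" %in% names(dt)) as.Date(dt$date) else local_civil_date(dt$timestamp, site)
    days <- sort(unique(d))
    drop <- days[runif(length(days)) < rates[[stream]]]
    bundle[[stream]] <- dt[!(d %in% drop)]
  }
  bundle
}

# Civil date of a local-face timestamp. Pure arithmetic (no strftime and
# no tz-database lookup): the face already is local civil time.
local_civil_date <- function(ts, site) {
  as.Date(floor(as.numeric(ts) / 86400), origin = "1970-01-01")
}
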