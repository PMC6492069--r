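# Single-component cosinor: OLS fit of a fixed-period cosine.
#
# The model is y = M + A*cos(2*pi*(t - phi)/P), linearized as
# y = M + b1*cos(wt) + b2*sin(wt) with A = sqrt(b1^2 + b2^2) and
# phi = atan2(b2, b1)/w mod P, so the acrophase is reported as the local
# clock time at which the fitted rhythm peaks.

#' Fit a 24-hour cosinor to a heart-rate window
#'
#' Ordinary least squares on up to 48 consecutive hours of samples. Time
#' enters as local clock hours; the window may span two civil days. Returns
#' the four rhythm parameters: mesor (rhythm-adjusted mean), amplitude
#' (half peak-to-trough), acrophase (clock time of peak, in `[0, period)`)
#' and R-squared (rhythm strength).
#'
#' A degenerate window (constant series, SST = 0) yields amplitude 0,
#' missing acrophase and R-squared 0. Fewer than `min_samples` points yield
#' an all-missing fit rather than an error, so missingness propagates into
#' the feature row.
#'
#' @param t_hours Numeric sample times in hours (any origin; only phase
#'   modulo `period` matters for the acrophase).
#' @param y Numeric heart-rate samples (bpm), same length as `t_hours`.
#' @param period Rhythm period in hours (default 24).
#' @param min_samples Minimum sample count for a valid fit. The default,
#'   half the expected minute-level samples of a 48-h window, encodes that
#'   the rhythm parameters are unreliable when most of the window is
#'   missing.
#' @return List of class `cosinor_fit`: `mesor`, `amplitude`, `acrophase`,
#'   `r_squared`, `n_samples`.
#' @examples
#' t <- seq(0, 48, by = 1 / 60)
#' y <- 70 + 10 * cos(2 * pi * (t - 15) / 24)
#' fit_cosinor(t, y)
#' @export
fit_cosinor <- function(t_hours, y, period = 24, min_samples = 1440) {
  ok <- is.finite(t_hours) & is.finite(y)
  t_hours <- t_hours[ok]; y <- y[ok]
  n <- length(y)
  empty <- structure(list(mesor = NA_real_, amplitude = NA_real_,
                          acrophase = NA_real_, r_squared = NA_real_,
                          n_samples = n), class = "cosinor_fit")
  if (n < max(3L, min_samples)) return(empty)
  if (diff(range(t_hours)) > 48 + 1e-9) {
    stop("cosinor window spans more than 48 hours")
  }
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t_hours), sin(w * t_hours))
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  if (anyNA(b)) return(empty) # rank-deficient design (e.g. single timepoint)
  sst <- sum((y - mean(y))^2)
  amp <- sqrt(b[2]^2 + b[3]^2)
  if (sst <= .Machine$double.eps * n) {
    # constant series: no rhythm, phase undefined
    return(structure(list(mesor = unname(b[1]), amplitude = 0,
                          acrophase = NA_real_, r_squared = 0,
                          n_samples = n), class = "cosinor_fit"))
  }
  sse <- sum(fit$residuals^2)
  acro <- (atan2(b[3], b[2]) / w) %% period
  structure(list(mesor = unname(b[1]), amplitude = unname(amp),
                 acrophase = unname(acro),
                 r_squared = max(0, min(1, 1 - sse / sst)),
                 n_samples = n), class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> mesor %.2f bpm, amplitude %.2f bpm, acrophase %s h, R^2 %s (n=%d)\n",
    x$mesor, x$amplitude,
    if (is.na(x$acrophase)) "NA" else sprintf("%.2f", x$acrophase),
    if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared),
    x$n_samples))
  invisible(x)
}
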