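#' Heart-rate slow component of a constant-work trial
#'
#' The scHR is the ordinary-least-squares slope of HR against time (in
#' minutes) from the fifth minute of exercise to the end of the trial,
#' expressed in bpm·min⁻¹. Endpoints are inclusive. Works on 5-s binned
#' `clean_series` data (the standard pipeline) or on any series with `t` and
#' `hr`.
#'
#' @param series a series with columns `t` (s) and `hr` (bpm).
#' @param onset exercise onset time, s.
#' @param fit_start start of the fitting window, s after onset (default
#'   300 s, i.e. the fifth minute).
#' @param fit_end end of the fitting window, s after onset; `NULL` uses the
#'   end of the series.
#' @return a list: `schr` (bpm·min⁻¹), `fit_r2` (`NA` when HR has no
#'   variance), `n_points`.
#' @export
compute_schr <- function(series, onset = 180, fit_start = 300,
                         fit_end = NULL) {
  t <- series$t
  hr <- series$hr
  ok <- !is.na(hr)
  fit_end <- fit_end %||% (max(t[ok]) - onset)
  w <- which(ok & t >= onset + fit_start - 1e-9 & t <= onset + fit_end + 1e-9)
  if (length(w) < 2L)
    stop_hrsc("fewer than 2 points in the scHR fitting window")
  x <- (t[w] - onset) / 60
  y <- hr[w]
  fit <- ols_line(x, y)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$resid^2) / sst else NA_real_
  list(schr = fit$b, fit_r2 = r2, n_points = length(w))
}

#' scHR relative to the fifth-minute V̇O₂
#'
#' @param schr absolute slow component, bpm·min⁻¹.
#' @param vo2_5min V̇O₂ at the fifth minute, mL·min⁻¹ (> 0).
#' @return scHR per L·min⁻¹ of fifth-minute V̇O₂.
#' @export
relative_schr <- function(schr, vo2_5min) {
  if (any(vo2_5min <= 0)) stop_hrsc("vo2_5min must be positive")
  schr / (vo2_5min / 1000)
}

#' Channel value "at" a given minute
#'
#' Mean of a channel over the window of `width` seconds ending at
#' `onset + 60 × minute` (the 30-s convention used for ramp maxima).
#'
#' @param series a series with `t` and the channel.
#' @param channel channel name.
#' @param minute minute of exercise.
#' @param onset exercise onset time, s.
#' @param width window width, s.
#' @return mean channel value over the window.
#' @export
window_value <- function(series, channel, minute, onset = 180, width = 30) {
  hi <- onset + 60 * minute
  lo <- hi - width
  t <- series$t
  # a 5-s tolerance accommodates binned grids whose last timestamp sits at
  # the final bin centre
  if (lo < min(t) - 5 - 1e-9 || hi > max(t) + 5 + 1e-9)
    stop_hrsc(sprintf("minute-%s window [%g, %g] s lies outside the series",
                      format(minute), lo, hi))
  w <- which(t >= lo - 1e-9 & t <= hi + 1e-9)
  y <- series[[channel]][w]
  y <- y[!is.na(y)]
  if (!length(y)) stop_hrsc("window contains no non-missing samples")
  mean(y)
}

#' Oxygen pulse at a given minute
#'
#' V̇O₂/HR in mL per beat, computed as the ratio of the window means of the
#' two channels over the same window (not the mean of per-breath ratios).
#'
#' @inheritParams window_value
#' @return oxygen pulse, mL·beat⁻¹.
#' @export
oxygen_pulse <- function(series, minute, onset = 180, width = 30) {
  window_value(series, "vo2", minute, onset, width) /
    window_value(series, "hr", minute, onset, width)
}

#' Relative exercise intensity to the RCP
#'
#' @param vo2_5min V̇O₂ at the fifth minute, mL·min⁻¹.
#' @param vo2_rcp V̇O₂ at the respiratory compensation point, mL·min⁻¹ (> 0).
#' @return intensity as %RCP.
#' @export
pct_rcp <- function(vo2_5min, vo2_rcp) {
  if (any(vo2_rcp <= 0)) stop_hrsc("vo2_rcp must be positive")
  100 * vo2_5min / vo2_rcp
}

#' Per-trial metrics table
#'
#' Computes the full set of per-trial quantities: scHR (absolute and relative
#' to the fifth-minute V̇O₂), oxygen pulse at the fifth (and, when the trial
#' lasts that long, ninth) minute, fifth-minute HR and V̇O₂, and %RCP.
#'
#' @param series a cleaned trial series.
#' @param subject the one-row subject tibble the trial belongs to.
#' @param onset exercise onset time, s.
#' @param trial_label optional label copied into the output.
#' @param fit_start,fit_end scHR fitting window, s after onset.
#' @return a one-row tibble: `subject_id`, `trial_label`, `schr`, `schr_rel`,
#'   `o2pulse_5`, `o2pulse_9`, `hr_5min`, `vo2_5min`, `pct_rcp`, `fit_r2`,
#'   `n_points`.
#' @export
trial_metrics <- function(series, subject, onset = 180,
                          trial_label = NA_character_, fit_start = 300,
                          fit_end = NULL) {
  stopifnot(nrow(subject) == 1L)
  fit <- compute_schr(series, onset = onset, fit_start = fit_start,
                      fit_end = fit_end)
  vo2_5 <- window_value(series, "vo2", 5, onset)
  hr_5 <- window_value(series, "hr", 5, onset)
  o2p_9 <- if (max(series$t) >= onset + 540 - 5) {
    oxygen_pulse(series, 9, onset)
  } else {
    NA_real_
  }
  vo2_rcp <- subject$rcp_frac * subject$vo2max_abs
  tibble::new_tibble(list(
    subject_id = subject$subject_id,
    trial_label = trial_label,
    schr = fit$schr,
    schr_rel = relative_schr(fit$schr, vo2_5),
    o2pulse_5 = vo2_5 / hr_5,
    o2pulse_9 = o2p_9,
    hr_5min = hr_5,
    vo2_5min = vo2_5,
    pct_rcp = pct_rcp(vo2_5, vo2_rcp),
    fit_r2 = fit$fit_r2,
    n_points = fit$n_points), nrow = 1L)
}
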