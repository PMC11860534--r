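#' Maximal parameters from a ramp test
#'
#' V̇O₂max and RERmax are the means of V̇O₂ and of the breath-wise
#' V̇CO₂/V̇O₂ ratio over the final 30 s before exhaustion; HRmax is the
#' highest heart rate achieved over the whole test.
#'
#' @param ramp a ramp series (raw [breath_series()] or `clean_series`) with
#'   channels `vo2`, `vco2`, `hr`.
#' @param exhaustion_t time of volitional exhaustion, s. The series must cover
#'   `[exhaustion_t − 30, exhaustion_t]` (a 5-s tolerance accommodates binned
#'   grids whose last timestamp sits at the final bin centre).
#' @return a list: `vo2max_abs` (mL·min⁻¹), `rer_max`, `hrmax` (bpm).
#' @export
max_params <- function(ramp, exhaustion_t) {
  t <- ramp$t
  if (min(t) > exhaustion_t - 30 + 1e-9 || max(t) < exhaustion_t - 5)
    stop_hrsc("series does not cover the final 30 s window before exhaustion")
  w <- which(t >= exhaustion_t - 30 - 1e-9 & t <= exhaustion_t + 1e-9)
  if (length(w) < 2L)
    stop_hrsc("final 30 s window contains fewer than 2 samples")
  list(vo2max_abs = mean(ramp$vo2[w]),
       rer_max = mean(ramp$vco2[w] / ramp$vo2[w]),
       hrmax = max(ramp$hr, na.rm = TRUE))
}

#' Fit the linear V̇O₂/time relation over a ramp segment
#'
#' @param series a ramp series with `t` and the chosen channel.
#' @param from,to absolute time bounds of the fitting window, s.
#' @param origin time subtracted from `t` before fitting, so the returned
#'   intercept refers to this origin (typically the ramp onset).
#' @param channel channel to fit.
#' @return a list `a` (intercept at `origin`), `b` (slope per s).
#' @export
fit_ramp_line <- function(series, from, to, origin = from, channel = "vo2") {
  w <- which(series$t >= from - 1e-9 & series$t <= to + 1e-9)
  y <- series[[channel]][w]
  ok <- !is.na(y)
  if (sum(ok) < 2L) stop_hrsc("fitting window contains fewer than 2 samples")
  fit <- ols_line(series$t[w][ok] - origin, y[ok])
  list(a = fit$a, b = fit$b)
}

#' Mean response time of V̇O₂ during a ramp
#'
#' The V̇O₂/time line fitted over the linear portion of the ramp is shifted in
#' time relative to the power ramp by the mean response time (MRT). The MRT is
#' computed as the time at which the fitted line reaches the steady-state
#' V̇O₂ measured during the pre-ramp baseline bout, minus the time at which
#' the ramp's power output equals the baseline power; a lagging V̇O₂ response
#' yields a positive MRT, and the estimate is clamped at 0.
#'
#' @param baseline_ss_vo2 steady-state V̇O₂ of the pre-ramp baseline bout,
#'   mL·min⁻¹.
#' @param baseline_po power output of that bout, W.
#' @param ramp_fit list `a`, `b` from [fit_ramp_line()], with time measured
#'   from the ramp onset.
#' @param ramp_rate ramp slope, W·min⁻¹.
#' @param po_start power output at the ramp onset, W.
#' @return MRT in seconds (≥ 0).
#' @export
compute_mrt <- function(baseline_ss_vo2, baseline_po, ramp_fit, ramp_rate,
                        po_start) {
  if (!is_scalar_number(ramp_fit$b) || ramp_fit$b <= 0)
    stop_hrsc("ramp fit slope must be positive: the fitted line never reaches the baseline steady state")
  t_po <- (baseline_po - po_start) * 60 / ramp_rate
  t_vo2 <- (baseline_ss_vo2 - ramp_fit$a) / ramp_fit$b
  max(0, t_vo2 - t_po)
}

#' Domain-anchored target V̇O₂
#'
#' Constant-trial intensities are anchored to the individual's resting V̇O₂,
#' gas exchange threshold (GET), respiratory compensation point (RCP) and
#' V̇O₂max: moderate trials sit at a fraction of the rest-to-GET difference,
#' heavy trials at a fraction of the GET-to-RCP difference and severe trials
#' at a fraction of the RCP-to-V̇O₂max difference.
#'
#' @param domain `"moderate"`, `"heavy"` or `"severe"`.
#' @param fraction fraction of the domain's V̇O₂ span, in (0, 1).
#' @param vo2_rest,vo2_get,vo2_rcp,vo2max_abs individual anchors, mL·min⁻¹,
#'   with `vo2_rest < vo2_get < vo2_rcp < vo2max_abs`.
#' @return target V̇O₂, mL·min⁻¹.
#' @export
target_vo2 <- function(domain, fraction, vo2_rest, vo2_get, vo2_rcp,
                       vo2max_abs) {
  if (!(vo2_rest < vo2_get && vo2_get < vo2_rcp && vo2_rcp < vo2max_abs))
    stop_hrsc("anchor ordering violated: need vo2_rest < GET < RCP < VO2max")
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction >= 1)
    stop_hrsc("fraction must lie in (0, 1)")
  switch(match.arg(domain, c("moderate", "heavy", "severe")),
         moderate = vo2_rest + fraction * (vo2_get - vo2_rest),
         heavy = vo2_get + fraction * (vo2_rcp - vo2_get),
         severe = vo2_rcp + fraction * (vo2max_abs - vo2_rcp))
}

#' Power output eliciting a target V̇O₂
#'
#' Inverts the MRT-corrected ramp V̇O₂/power relation. Below the GET the
#' inversion is linear in the ramp slope; above the GET an optional
#' slow-component gain `sc_gain` (mL·min⁻¹·W⁻¹, default 0) is added to the
#' slope for the above-GET portion, lowering the prescribed power relative to
#' the naive inversion to compensate for the excess V̇O₂ that develops at
#' heavy and severe work rates.
#'
#' @param target target V̇O₂, mL·min⁻¹ (must exceed the baseline steady
#'   state).
#' @param ramp a list with `ramp_slope` (mL·min⁻¹·W⁻¹), `baseline_po` (W) and
#'   `baseline_ss_vo2` (mL·min⁻¹), e.g. an augmented [max_params()] result.
#' @param vo2_get V̇O₂ at the GET, mL·min⁻¹ (`NULL` disables the above-GET
#'   correction).
#' @param sc_gain additional V̇O₂ cost per watt above the GET, mL·min⁻¹·W⁻¹.
#' @return power output, W.
#' @export
vo2_to_po <- function(target, ramp, vo2_get = NULL, sc_gain = 0) {
  slope <- ramp$ramp_slope
  if (!is_scalar_number(slope) || slope <= 0)
    stop_hrsc("ramp slope must be positive")
  if (sc_gain < 0) stop_hrsc("sc_gain must be non-negative")
  if (target <= ramp$baseline_ss_vo2)
    stop_hrsc("target must exceed the baseline steady-state VO2")
  po_lin <- function(v) ramp$baseline_po + (v - ramp$baseline_ss_vo2) / slope
  if (is.null(vo2_get) || target <= vo2_get || sc_gain == 0) {
    po_lin(target)
  } else {
    po_lin(vo2_get) + (target - vo2_get) / (slope + sc_gain)
  }
}

#' Prescribe the constant-work-rate trials for a subject
#'
#' Step 1 prescribes six 9-min trials at 33% and 66% of each intensity
#' domain's span (labels M1, M2, H1, H2, S1, S2); Step 2 prescribes three
#' trials at 50% of each span with durations of 15, 12 and 9 min for the
#' moderate, heavy and severe domain.
#'
#' @param subject a one-row subject tibble.
#' @param step 1 (development protocol) or 2 (validation protocol).
#' @param sc_gain passed to [vo2_to_po()] for the above-GET correction.
#' @return a tibble with `trial_label`, `domain`, `fraction`, `target_vo2`,
#'   `target_po`, `pct_rcp_nominal` and `duration` (s, post-onset).
#' @export
prescribe_trials <- function(subject, step = 1, sc_gain = 0) {
  stopifnot(nrow(subject) == 1L)
  vo2_get <- subject$get_frac * subject$vo2max_abs
  vo2_rcp <- subject$rcp_frac * subject$vo2max_abs
  if (step == 1) {
    plan <- tibble::tibble(
      trial_label = c("M1", "M2", "H1", "H2", "S1", "S2"),
      domain = rep(c("moderate", "heavy", "severe"), each = 2L),
      fraction = rep(c(0.33, 0.66), times = 3L),
      duration = 540)
  } else if (step == 2) {
    plan <- tibble::tibble(
      trial_label = c("M", "H", "S"),
      domain = c("moderate", "heavy", "severe"),
      fraction = 0.50,
      duration = c(900, 720, 540))
  } else {
    stop_hrsc("step must be 1 or 2")
  }
  ramp <- list(ramp_slope = subject$vo2_po_slope, baseline_po = 0,
               baseline_ss_vo2 = subject$vo2_rest)
  plan$target_vo2 <- vapply(seq_len(nrow(plan)), function(i) {
    target_vo2(plan$domain[i], plan$fraction[i], subject$vo2_rest, vo2_get,
               vo2_rcp, subject$vo2max_abs)
  }, numeric(1))
  plan$target_po <- vapply(plan$target_vo2, vo2_to_po, numeric(1),
                           ramp = ramp, vo2_get = vo2_get, sc_gain = sc_gain)
  plan$pct_rcp_nominal <- 100 * plan$target_vo2 / vo2_rcp
  plan
}
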