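#' Measurement-noise configuration
#'
#' Per-breath measurement noise and trial-level variability for the synthetic
#' generator. Defaults: HR noise 2 bpm per breath plus a day-to-day HR offset
#' of 1.7 bpm SD (so that the within-subject freewheeling HR coefficient of
#' variation lands near the reported 2.7%), gas-channel noise 3% of the signal,
#' scHR residual SD 0.61 bpm·min⁻¹ (the prediction equation's standard error of
#' estimate), and breath intervals Uniform(2, 4) s.
#'
#' @param hr_sd additive per-breath HR noise SD, bpm.
#' @param vo2_cv,vco2_cv multiplicative gas-channel noise, coefficient of
#'   variation.
#' @param hr_day_sd SD of a constant per-trial HR offset, bpm (day-to-day
#'   variability).
#' @param sigma_resid SD of the residual added to the equation-predicted scHR
#'   when generating a trial's true slope, bpm·min⁻¹.
#' @param breath_min,breath_max bounds of the uniform breath-interval model, s.
#' @param truncate_negative if `TRUE`, negative generated slopes (prediction
#'   and prediction-plus-residual) are truncated at 0. Default `FALSE`: the
#'   generating model is kept linear so that regression recovery of the
#'   equation is unbiased; see the methods vignette.
#'
#' @return a list of class `noise_config`.
#' @export
noise_config <- function(hr_sd = 2, vo2_cv = 0.03, vco2_cv = 0.03,
                         hr_day_sd = 1.7, sigma_resid = 0.61,
                         breath_min = 2, breath_max = 4,
                         truncate_negative = FALSE) {
  structure(list(hr_sd = hr_sd, vo2_cv = vo2_cv, vco2_cv = vco2_cv,
                 hr_day_sd = hr_day_sd, sigma_resid = sigma_resid,
                 breath_min = breath_min, breath_max = breath_max,
                 truncate_negative = truncate_negative),
            class = "noise_config")
}

#' @rdname noise_config
#' @export
zero_noise <- function() {
  noise_config(hr_sd = 0, vo2_cv = 0, vco2_cv = 0, hr_day_sd = 0,
               sigma_resid = 0)
}

#' Kinetics configuration for constant-work trials
#'
#' Mono-exponential time constants by intensity domain (invented defaults,
#' configurable), the HR primary-gain calibration, and steady-state
#' respiratory exchange ratios used for the V̇CO₂ channel.
#'
#' The primary HR amplitude maps the V̇O₂ reserve fraction to the HR reserve
#' fraction affinely (`hr_gain_intercept + hr_gain_slope × fraction`); the
#' default 0.08 + 0.80·f reproduces the reported 5th-minute HR across the six
#' constant-work intensities.
#'
#' @param tau_vo2,tau_hr named vectors of time constants (s) per domain.
#' @param hr_gain_intercept,hr_gain_slope affine map from V̇O₂ reserve
#'   fraction to HR reserve fraction.
#' @param rer steady-state respiratory exchange ratio per domain.
#' @return a list of class `kinetics_config`.
#' @export
kinetics_config <- function(tau_vo2 = c(moderate = 30, heavy = 35, severe = 40),
                            tau_hr = c(moderate = 35, heavy = 40, severe = 45),
                            hr_gain_intercept = 0.08, hr_gain_slope = 0.80,
                            rer = c(moderate = 0.85, heavy = 0.95, severe = 1.05)) {
  structure(list(tau_vo2 = tau_vo2, tau_hr = tau_hr,
                 hr_gain_intercept = hr_gain_intercept,
                 hr_gain_slope = hr_gain_slope, rer = rer),
            class = "kinetics_config")
}

#' Construct a breath-by-breath series
#'
#' A thin tibble wrapper holding one trial's time-stamped samples: `t` (s,
#' strictly increasing, possibly irregular), `vo2`, `vco2` (mL·min⁻¹), `hr`
#' (bpm), `po` (W), with trial metadata kept as an attribute.
#'
#' @param t,vo2,vco2,hr,po numeric channels of equal length.
#' @param subject_id,trial_label,domain metadata strings.
#' @return a tibble of class `breath_series`.
#' @export
breath_series <- function(t, vo2, vco2, hr, po,
                          subject_id = NA_character_,
                          trial_label = NA_character_,
                          domain = NA_character_) {
  lens <- lengths(list(vo2, vco2, hr, po))
  if (any(lens != length(t)))
    stop_hrsc("all channels must have the same length as t")
  if (length(t) > 1 && any(diff(t) <= 0))
    stop_hrsc("t must be strictly increasing")
  x <- tibble::new_tibble(list(t = as.numeric(t), vo2 = as.numeric(vo2),
                               vco2 = as.numeric(vco2), hr = as.numeric(hr),
                               po = as.numeric(po)), nrow = length(t))
  attr(x, "meta") <- list(subject_id = subject_id, trial_label = trial_label,
                          domain = domain)
  class(x) <- c("breath_series", class(x))
  x
}

#' @rdname breath_series
#' @param x a `breath_series`.
#' @export
series_meta <- function(x) attr(x, "meta")

# Irregular breath times on [a, b) with anchors at both ends of each segment.
breath_times <- function(anchors, bmin, bmax) {
  out <- numeric(0)
  for (i in seq_len(length(anchors) - 1L)) {
    a <- anchors[i]; b <- anchors[i + 1L]
    nmax <- ceiling((b - a) / bmin) + 1L
    ts <- a + cumsum(stats::runif(nmax, bmin, bmax))
    ts <- ts[ts < b - 1e-9]
    out <- c(out, a, ts)
  }
  c(out, anchors[length(anchors)])
}

# Intensity domain of a target V̇O₂ for a subject.
intensity_domain <- function(subject, target_vo2) {
  vo2_get <- subject$get_frac * subject$vo2max_abs
  vo2_rcp <- subject$rcp_frac * subject$vo2max_abs
  if (target_vo2 < vo2_get) "moderate" else if (target_vo2 < vo2_rcp) "heavy" else "severe"
}

#' Simulate a constant-work-rate trial
#'
#' Emits a 3-min freewheeling baseline followed by an instantaneous step to
#' the target power output. V̇O₂ rises mono-exponentially to the target; HR
#' rises mono-exponentially to its primary steady state and, from
#' `sc_onset` (default 300 s) after exercise onset, drifts linearly at the
#' trial's true slow-component slope. The true slope is the prediction
#' equation evaluated at the trial's nominal %RCP, age and sex, plus a
#' Normal(0, `sigma_resid`) residual. The primary HR component is treated as
#' complete at the slow-component onset so that the post-onset trace is
#' exactly linear; HR is capped at the subject's HRmax. Breath samples are
#' emitted at the trial start, exercise onset, slow-component onset and trial
#' end, with Uniform(`breath_min`, `breath_max`) s intervals in between.
#'
#' @param subject a one-row subject tibble, see [generate_population()].
#' @param target_vo2 target steady-state V̇O₂, mL·min⁻¹; must exceed resting
#'   V̇O₂ and not exceed V̇O₂max.
#' @param duration exercise duration after onset, s (≥ 360).
#' @param seed integer seed or `NULL`.
#' @param noise a [noise_config()].
#' @param kinetics a [kinetics_config()].
#' @param baseline freewheeling baseline duration, s.
#' @param sc_onset slow-component onset after exercise onset, s.
#'
#' @return a list with `series` (a [breath_series()]) and `truth`, the
#'   ground-truth ledger: `true_schr` (bpm·min⁻¹), `true_vo2_ss`, `tau_hr`,
#'   `tau_vo2`, `hr_amplitude`, `pct_rcp_nominal`, `domain`, `target_po`,
#'   `hr_day_offset`, `outlier_indices` (empty; filled by
#'   [inject_aberrant()]).
#' @export
simulate_constant_trial <- function(subject, target_vo2, duration = 540,
                                    seed = NULL, noise = noise_config(),
                                    kinetics = kinetics_config(),
                                    baseline = 180, sc_onset = 300) {
  stopifnot(nrow(subject) == 1L)
  if (!is_scalar_number(target_vo2) || target_vo2 <= subject$vo2_rest)
    stop_hrsc("target_vo2 must exceed resting VO2")
  if (target_vo2 > subject$vo2max_abs)
    stop_hrsc("target_vo2 above VO2max: the trial is not sustainable")
  if (!is_scalar_number(duration) || duration < 360)
    stop_hrsc("duration must be at least 360 s")

  dom <- intensity_domain(subject, target_vo2)
  tau_vo2 <- kinetics$tau_vo2[[dom]]
  tau_hr <- kinetics$tau_hr[[dom]]
  vo2_rcp <- subject$rcp_frac * subject$vo2max_abs
  pct_rcp_nominal <- 100 * target_vo2 / vo2_rcp

  local_seed(seed, {
    mu <- predict_schr(pct_rcp_nominal, subject$age, subject$sex)
    if (noise$truncate_negative) mu <- max(mu, 0)
    true_schr <- mu + stats::rnorm(1, 0, noise$sigma_resid)
    if (noise$truncate_negative) true_schr <- max(true_schr, 0)

    t <- breath_times(c(0, baseline, baseline + sc_onset, baseline + duration),
                      noise$breath_min, noise$breath_max)
    u <- t - baseline  # time since exercise onset

    A_vo2 <- target_vo2 - subject$vo2_rest
    vo2_sig <- subject$vo2_rest +
      ifelse(u > 0, A_vo2 * (1 - exp(-u / tau_vo2)), 0)

    resfrac <- (target_vo2 - subject$vo2_rest) /
      (subject$vo2max_abs - subject$vo2_rest)
    hr_frac <- min(1, kinetics$hr_gain_intercept +
                     kinetics$hr_gain_slope * resfrac)
    A_hr <- hr_frac * (subject$hrmax - subject$hr_rest)
    prim <- A_hr * (1 - exp(-pmin(u, sc_onset) / tau_hr))
    slow <- ifelse(u > sc_onset, true_schr * (u - sc_onset) / 60, 0)
    hr_sig <- pmin(subject$hr_rest + ifelse(u > 0, prim + slow, 0),
                   subject$hrmax)

    rer_ss <- kinetics$rer[[dom]]
    vco2_sig <- rer_ss * vo2_sig

    target_po <- (target_vo2 - subject$vo2_rest) / subject$vo2_po_slope
    po <- ifelse(u > 0, target_po, 0)

    n <- length(t)
    day <- stats::rnorm(1, 0, noise$hr_day_sd)
    hr <- pmax(hr_sig + day + stats::rnorm(n, 0, noise$hr_sd), 25)
    vo2 <- pmax(vo2_sig * (1 + stats::rnorm(n, 0, noise$vo2_cv)), 1)
    vco2 <- pmax(vco2_sig * (1 + stats::rnorm(n, 0, noise$vco2_cv)), 1)

    series <- breath_series(t, vo2, vco2, hr, po,
                            subject_id = subject$subject_id,
                            domain = dom)
    truth <- list(true_schr = true_schr, true_vo2_ss = target_vo2,
                  tau_hr = tau_hr, tau_vo2 = tau_vo2, hr_amplitude = A_hr,
                  pct_rcp_nominal = pct_rcp_nominal, domain = dom,
                  target_po = target_po, hr_day_offset = day,
                  outlier_indices = integer(0))
    list(series = series, truth = truth)
  })
}

#' Simulate a ramp incremental test
#'
#' A steady warm-up at `baseline_po` followed by a linear power ramp to
#' volitional exhaustion. The V̇O₂ response lags the instantaneous demand by
#' the subject's mean response time (`mrt`) and plateaus at V̇O₂max for
#' `plateau_dur` seconds before exhaustion; HR rises with the V̇O₂ reserve
#' fraction to HRmax, and the respiratory exchange ratio climbs from 0.80 at
#' rest to 1.15 at V̇O₂max.
#'
#' @inheritParams simulate_constant_trial
#' @param baseline_po warm-up power output, W.
#' @param ramp_rate ramp slope, W·min⁻¹.
#' @param baseline_dur warm-up duration, s.
#' @param plateau_dur plateau sustained at V̇O₂max before exhaustion, s.
#'
#' @return a list with `series` (a [breath_series()]) and `truth`:
#'   `exhaustion_t` (s), `ramp_onset` (s), `baseline_ss_vo2` (mL·min⁻¹),
#'   `mrt` (s), `vo2max_abs`, `hrmax`, `ramp_rate`, `po_start`.
#' @export
simulate_ramp <- function(subject, seed = NULL, noise = noise_config(),
                          baseline_po = 75, ramp_rate = 25,
                          baseline_dur = 360, plateau_dur = 30) {
  stopifnot(nrow(subject) == 1L)
  demand <- function(po) subject$vo2_rest + subject$vo2_po_slope * po
  base_ss <- demand(baseline_po)
  if (base_ss >= subject$vo2max_abs)
    stop_hrsc("baseline power demand exceeds VO2max; lower baseline_po")
  t0 <- baseline_dur
  t_max <- t0 + subject$mrt +
    (subject$vo2max_abs - base_ss) * 60 / (subject$vo2_po_slope * ramp_rate)
  exhaustion_t <- t_max + plateau_dur

  local_seed(seed, {
    t <- breath_times(c(0, t0, exhaustion_t), noise$breath_min, noise$breath_max)
    po <- ifelse(t > t0, baseline_po + ramp_rate / 60 * (t - t0), baseline_po)
    lagged <- pmax(t - subject$mrt, t0)
    po_lag <- ifelse(t > t0, baseline_po + ramp_rate / 60 * (lagged - t0),
                     baseline_po)
    vo2_sig <- pmin(demand(po_lag), subject$vo2max_abs)
    frac <- (vo2_sig - subject$vo2_rest) /
      (subject$vo2max_abs - subject$vo2_rest)
    hr_sig <- pmin(subject$hr_rest + frac * (subject$hrmax - subject$hr_rest),
                   subject$hrmax)
    rer_sig <- 0.80 + 0.35 * frac
    vco2_sig <- rer_sig * vo2_sig

    n <- length(t)
    day <- stats::rnorm(1, 0, noise$hr_day_sd)
    hr <- pmax(hr_sig + day + stats::rnorm(n, 0, noise$hr_sd), 25)
    vo2 <- pmax(vo2_sig * (1 + stats::rnorm(n, 0, noise$vo2_cv)), 1)
    vco2 <- pmax(vco2_sig * (1 + stats::rnorm(n, 0, noise$vco2_cv)), 1)

    series <- breath_series(t, vo2, vco2, hr, po,
                            subject_id = subject$subject_id,
                            trial_label = "ramp")
    truth <- list(exhaustion_t = exhaustion_t, ramp_onset = t0,
                  baseline_ss_vo2 = base_ss, mrt = subject$mrt,
                  vo2max_abs = subject$vo2max_abs, hrmax = subject$hrmax,
                  ramp_rate = ramp_rate, po_start = baseline_po)
    list(series = series, truth = truth)
  })
}

#' Inject aberrant data points
#'
#' Displaces randomly chosen samples (outside the protected 0–180 s
#' post-onset transition) away from the local trend by
#' `magnitude` local standard deviations, emulating the aberrant breaths that
#' the cleaning stage must remove. The displaced value is set to the local
#' linear-trend prediction plus or minus `magnitude × local SD`, where the
#' local SD is the residual SD of a linear fit over the `window` surrounding
#' samples, floored at `sd_floor` to keep displacements non-degenerate on
#' noiseless signals.
#'
#' @param series a [breath_series()].
#' @param rate fraction of eligible samples to displace, in `[0, 0.2)`.
#' @param magnitude displacement in multiples of the local SD (> 3).
#' @param seed integer seed or `NULL`.
#' @param onset exercise onset time, s.
#' @param channels channels to displace.
#' @param window local fitting window, samples (odd).
#' @param sd_floor lower bound on the local SD, channel units.
#'
#' @return a list with `series` (displaced copy), `outlier_indices` (sorted
#'   sample positions) and `audit`, a tibble with one row per (index, channel)
#'   recording the local SD and realised displacement.
#' @export
inject_aberrant <- function(series, rate, magnitude, seed = NULL, onset = 180,
                            channels = c("vo2", "vco2", "hr"),
                            window = 11L, sd_floor = 1) {
  if (!is_scalar_number(rate) || rate < 0 || rate >= 0.2)
    stop_hrsc("rate must be in [0, 0.2)")
  if (!is_scalar_number(magnitude) || magnitude <= 3)
    stop_hrsc("magnitude must exceed 3 local SDs")
  u <- series$t - onset
  eligible <- which(u <= 0 | u > 180)
  n_out <- round(rate * length(eligible))
  if (n_out == 0L) {
    return(list(series = series, outlier_indices = integer(0),
                audit = tibble::tibble(index = integer(0), channel = character(0),
                                       local_sd = numeric(0),
                                       displacement = numeric(0))))
  }
  local_seed(seed, {
    idx <- sort(sample(eligible, n_out))
    sgn <- sample(c(-1, 1), n_out, replace = TRUE)
    out <- series
    half <- window %/% 2L
    audit <- vector("list", length(channels))
    for (ci in seq_along(channels)) {
      ch <- channels[ci]
      y <- series[[ch]]
      loc_sd <- numeric(n_out)
      disp <- numeric(n_out)
      for (j in seq_along(idx)) {
        i <- idx[j]
        w <- max(1L, i - half):min(length(y), i + half)
        fit <- ols_line(series$t[w], y[w])
        pred <- fit$a + fit$b * series$t[i]
        s <- max(fit$sigma, sd_floor)
        newval <- pred + sgn[j] * magnitude * s
        disp[j] <- newval - pred
        loc_sd[j] <- s
        out[[ch]][i] <- newval
      }
      audit[[ci]] <- tibble::tibble(index = idx, channel = ch,
                                    local_sd = loc_sd, displacement = disp)
    }
    list(series = out, outlier_indices = idx, audit = do.call(rbind, audit))
  })
}
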