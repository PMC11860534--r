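# Fixtures built in code: a deterministic subject and constructed series.

# A subject with round numbers so domain anchors are easy to reason about.
fixed_subject <- function(age = 35, sex = "male", vo2max_abs = 3000,
                          rcp_frac = 0.80, get_frac = 0.60, vo2_rest = 300,
                          hr_rest = 60, hrmax = 185, vo2_po_slope = 10,
                          mrt = 40, body_mass = 75) {
  tibble::tibble(subject_id = "T001", age_group = "young", age = age,
                 sex = sex, body_mass = body_mass, height = 178,
                 vo2_rest = vo2_rest, vo2max_abs = vo2max_abs,
                 vo2max_rel = vo2max_abs / body_mass, hrmax = hrmax,
                 hr_rest = hr_rest, get_frac = get_frac, rcp_frac = rcp_frac,
                 vo2_po_slope = vo2_po_slope, mrt = mrt)
}

# Breath series with identical values written into every channel.
flat_series <- function(t, value) {
  breath_series(t, vo2 = value, vco2 = value, hr = value, po = value)
}

# Noise-free piecewise-linear trial-shaped series: constant baseline before
# `onset`, then a line in each channel. Exactly consistent with the cleaner's
# two linear fitting windows.
linear_trial_series <- function(t = seq(0, 720, by = 3), onset = 180,
                                hr0 = 80, hr_slope = 0.02,
                                vo20 = 1500, vo2_slope = 0.5) {
  u <- pmax(t - onset, 0)
  breath_series(t,
                vo2 = vo20 + vo2_slope * u,
                vco2 = 0.9 * (vo20 + vo2_slope * u),
                hr = hr0 + hr_slope * u,
                po = ifelse(u > 0, 150, 0))
}
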