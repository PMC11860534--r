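# Ramp-derived maxima, mean response time, and intensity anchoring.

test_that("max_params averages the final 30 s and takes the HR maximum", {
  t <- 0:600
  s <- breath_series(t, vo2 = rep(3000, 601), vco2 = 1.15 * rep(3000, 601),
                     hr = pmin(100 + 0.15 * t, 185), po = t)
  mp <- max_params(s, exhaustion_t = 600)
  expect_equal(mp$vo2max_abs, 3000)
  expect_equal(mp$rer_max, 1.15)
  expect_equal(mp$hrmax, max(s$hr))
  expect_error(max_params(s, exhaustion_t = 2000), "30 s")
})

test_that("ramp maxima are recovered from a noisy synthetic ramp", {
  subj <- fixed_subject(vo2max_abs = 2800, vo2_po_slope = 10)
  noise <- noise_config(vo2_cv = 50 / 2800, hr_sd = 0, hr_day_sd = 0,
                        vco2_cv = 0)
  sim <- simulate_ramp(subj, seed = 3, noise = noise, ramp_rate = 25)
  mp <- max_params(sim$series, sim$truth$exhaustion_t)
  # plateau noise SD 50, ~10 breaths in the window: 3 SE of the window mean
  expect_lt(abs(mp$vo2max_abs - 2800), 3 * 50 / sqrt(10))
})

test_that("compute_mrt recovers the configured lag and is rate-invariant", {
  subj <- fixed_subject(mrt = 40)
  for (rate in c(20, 40)) {
    sim <- simulate_ramp(subj, seed = 6, noise = zero_noise(),
                         baseline_po = 75, ramp_rate = rate)
    tr <- sim$truth
    # fit over the purely lagged linear portion of the ramp
    fit <- fit_ramp_line(sim$series, from = tr$ramp_onset + 120,
                         to = tr$exhaustion_t - tr$mrt - 60,
                         origin = tr$ramp_onset)
    mrt <- compute_mrt(tr$baseline_ss_vo2, baseline_po = 75, ramp_fit = fit,
                       ramp_rate = rate, po_start = 75)
    expect_equal(mrt, 40, tolerance = 1e-6)
  }

  z <- fixed_subject(mrt = 0)
  simz <- simulate_ramp(z, seed = 6, noise = zero_noise(), ramp_rate = 25)
  fitz <- fit_ramp_line(simz$series, from = simz$truth$ramp_onset + 60,
                        to = simz$truth$exhaustion_t - 60,
                        origin = simz$truth$ramp_onset)
  mrtz <- compute_mrt(simz$truth$baseline_ss_vo2, 75, fitz, 25, 75)
  expect_equal(mrtz, 0, tolerance = 1e-6)

  expect_error(compute_mrt(1000, 75, list(a = 2000, b = -1), 25, 75),
               "slope")
})

test_that("target_vo2 implements the domain-anchored fractions", {
  expect_equal(target_vo2("moderate", 0.33, 300, 1500, 2100, 3000), 696)
  expect_equal(target_vo2("severe", 0.66, 300, 1500, 2500, 3000), 2830)
  expect_equal(target_vo2("heavy", 0.50, 300, 1500, 2100, 3000), 1800)
  expect_error(target_vo2("heavy", 0.5, 300, 2500, 2100, 3000), "ordering")

  # strictly increasing in fraction, bounded by the domain
  f <- seq(0.1, 0.9, by = 0.1)
  tv <- vapply(f, function(x) target_vo2("heavy", x, 300, 1500, 2100, 3000),
               numeric(1))
  expect_true(all(diff(tv) > 0))
  expect_true(all(tv > 1500 & tv < 2100))
})

test_that("vo2_to_po inverts the ramp relation and applies the above-GET
          slow-component correction", {
  ramp <- list(ramp_slope = 10, baseline_po = 50, baseline_ss_vo2 = 900)
  expect_equal(vo2_to_po(1900, ramp), 150)
  naive <- vo2_to_po(2500, ramp, vo2_get = 1800, sc_gain = 0)
  corr <- vo2_to_po(2500, ramp, vo2_get = 1800, sc_gain = 1.5)
  expect_lt(corr, naive)
  # monotone in the target
  targets <- seq(1000, 2800, by = 200)
  po <- vapply(targets, vo2_to_po, numeric(1), ramp = ramp,
               vo2_get = 1800, sc_gain = 1.5)
  expect_true(all(diff(po) > 0))
  expect_error(vo2_to_po(800, ramp), "baseline")
})

test_that("prescription round-trips through the generator's VO2 demand", {
  subj <- fixed_subject()
  plan <- prescribe_trials(subj, step = 1)
  expect_equal(plan$trial_label, c("M1", "M2", "H1", "H2", "S1", "S2"))
  # the generator's steady state at the prescribed power equals the target
  demand <- subj$vo2_rest + subj$vo2_po_slope * plan$target_po
  expect_equal(demand, plan$target_vo2, tolerance = 1e-9)
  # domain boundaries respected
  vo2_get <- subj$get_frac * subj$vo2max_abs
  vo2_rcp <- subj$rcp_frac * subj$vo2max_abs
  expect_true(all(plan$target_vo2[plan$domain == "moderate"] < vo2_get))
  expect_true(all(plan$target_vo2[plan$domain == "heavy"] > vo2_get &
                    plan$target_vo2[plan$domain == "heavy"] < vo2_rcp))
  expect_true(all(plan$target_vo2[plan$domain == "severe"] > vo2_rcp))

  plan2 <- prescribe_trials(subj, step = 2)
  expect_equal(plan2$fraction, rep(0.5, 3))
  expect_equal(plan2$duration, c(900, 720, 540))

  # simulated 5th-minute VO2 lands within 2% of the target
  sim <- simulate_constant_trial(subj, plan$target_vo2[3], seed = 2,
                                 noise = zero_noise())
  vo2_5 <- window_value(clean_trial(sim$series), "vo2", 5)
  expect_lt(abs(vo2_5 / plan$target_vo2[3] - 1), 0.02)
})
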