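# Synthetic subjects and trials: stratification, determinism, ground truth.

test_that("population matches the requested strata exactly", {
  pop <- generate_population(65, seed = 11)
  expect_equal(nrow(pop), 65)
  tab <- table(pop$age_group)
  expect_equal(unname(tab[c("young", "middle", "elderly")]),
               c(23, 22, 20), ignore_attr = TRUE)
  fem <- table(pop$age_group[pop$sex == "female"])
  expect_equal(unname(fem[c("young", "middle", "elderly")]),
               c(12, 12, 10), ignore_attr = TRUE)

  # largest-remainder apportionment holds for totals that do not divide evenly
  pop2 <- generate_population(10, seed = 3)
  expect_equal(nrow(pop2), 10)
})

test_that("population generation is deterministic and invariants hold", {
  p1 <- generate_population(40, seed = 7)
  p2 <- generate_population(40, seed = 7)
  expect_identical(p1, p2)

  pop <- generate_population(300, seed = 8)
  expect_true(all(pop$get_frac > 0 & pop$get_frac < pop$rcp_frac &
                    pop$rcp_frac < 1))
  expect_true(all(pop$vo2_rest < pop$get_frac * pop$vo2max_abs))
  expect_true(all(abs(pop$vo2max_abs - pop$vo2max_rel * pop$body_mass) < 1e-9))
  expect_true(all(pop$hr_rest < pop$hrmax))
  expect_true(all(pop$age >= 18))
})

test_that("population moments converge to the configured means", {
  pop <- generate_population(10000, seed = 21,
                             strata = step2_strata())  # half female
  fem <- pop$vo2max_rel[pop$sex == "female"]
  # configured female mean 41.4, SD 7.1 (truncation effect negligible here)
  se <- 7.1 / sqrt(length(fem))
  expect_lt(abs(mean(fem) - 41.4), 2 * se)
  mal <- pop$vo2max_rel[pop$sex == "male"]
  expect_lt(abs(mean(mal) - 51.0), 2 * 11.0 / sqrt(length(mal)))
})

test_that("invalid strata are rejected", {
  bad <- step1_strata()
  bad$prop[1] <- -0.1
  expect_error(generate_population(10, seed = 1, strata = bad), "strata")
})

test_that("constant-trial truth follows the prediction equation", {
  # subject whose RCP VO2 is 2400, so a 2400 mL/min target sits at 100 %RCP
  subj <- fixed_subject(age = 35, sex = "male", vo2max_abs = 3000,
                        rcp_frac = 0.80)
  sim <- simulate_constant_trial(subj, 2400, seed = 1, noise = zero_noise())
  expect_equal(sim$truth$true_schr, -0.0514 + 2.40 - 0.602, tolerance = 1e-12)

  fem <- fixed_subject(age = 35, sex = "female", vo2max_abs = 3000,
                       rcp_frac = 0.80)
  simf <- simulate_constant_trial(fem, 2400, seed = 1, noise = zero_noise())
  expect_equal(simf$truth$true_schr, 1.7466 - 0.347, tolerance = 1e-12)
})

test_that("trial construction respects duration and breath-interval bounds", {
  subj <- fixed_subject()
  sim <- simulate_constant_trial(subj, 2000, duration = 540, seed = 2)
  t <- sim$series$t
  expect_lte(max(t), 540 + 180)
  expect_gte(nrow(sim$series), (540 + 180) / 4)
  expect_true(all(diff(t) > 0))
  expect_true(all(sim$series$hr > 0 & sim$series$vo2 > 0))

  s2 <- simulate_constant_trial(subj, 2000, duration = 540, seed = 2)
  expect_identical(sim$series, s2$series)  # bit-identical under the same seed

  expect_error(simulate_constant_trial(subj, 3500, seed = 1), "VO2max")
  expect_error(simulate_constant_trial(subj, 2000, duration = 200, seed = 1),
               "360")
})

test_that("noiseless trials close the loop: slope and steady state recovered", {
  subj <- fixed_subject()
  for (target in c(1200, 2100, 2700)) {
    sim <- simulate_constant_trial(subj, target, seed = 5,
                                   noise = zero_noise())
    est <- compute_schr(sim$series)
    expect_lt(abs(est$schr - sim$truth$true_schr), 1e-6)
    cs <- clean_trial(sim$series)
    vo2_5 <- window_value(cs, "vo2", 5)
    expect_lt(abs(vo2_5 / target - 1), 0.005)
  }
})

test_that("aberrant injection is controlled, audited and deterministic", {
  subj <- fixed_subject()
  sim <- simulate_constant_trial(subj, 2000, seed = 9)

  none <- inject_aberrant(sim$series, rate = 0, magnitude = 5, seed = 1)
  expect_identical(none$series, sim$series)
  expect_length(none$outlier_indices, 0)

  inj <- inject_aberrant(sim$series, rate = 0.02, magnitude = 5, seed = 4)
  u <- sim$series$t - 180
  n_eligible <- sum(u <= 0 | u > 180)
  expect_equal(length(inj$outlier_indices), round(0.02 * n_eligible))
  # no displacement inside the protected transition
  expect_false(any(u[inj$outlier_indices] > 0 & u[inj$outlier_indices] <= 180))
  # every displacement is exactly magnitude local SDs
  expect_true(all(abs(inj$audit$displacement) >=
                    5 * inj$audit$local_sd - 1e-9))

  inj2 <- inject_aberrant(sim$series, rate = 0.02, magnitude = 5, seed = 4)
  expect_identical(inj$outlier_indices, inj2$outlier_indices)
  expect_identical(inj$series, inj2$series)

  expect_error(inject_aberrant(sim$series, rate = 0.5, magnitude = 5),
               "rate")
  expect_error(inject_aberrant(sim$series, rate = 0.01, magnitude = 2),
               "magnitude")
})
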