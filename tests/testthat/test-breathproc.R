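# Breath-by-breath cleaning: outlier rejection, interpolation, binning.

test_that("a line-consistent series yields zero removals", {
  s <- linear_trial_series()
  res <- remove_aberrant(s)
  expect_identical(unname(lengths(res$removed)), rep(0L, 3))
  expect_identical(res$series, s)
})

test_that("a displaced point in the steady-state window is removed, and the
          transition is protected", {
  s <- linear_trial_series()
  i_steady <- which.min(abs(s$t - 580))   # onset + 400 s
  s_out <- s
  s_out$hr[i_steady] <- s_out$hr[i_steady] + 12  # any clear displacement
  res <- remove_aberrant(s_out)
  expect_identical(res$removed$hr, i_steady)
  expect_identical(res$removed$vo2, integer(0))
  expect_true(is.na(res$series$hr[i_steady]))

  # same displacement at onset + 100 s: inside the protected transition
  i_trans <- which.min(abs(s$t - 280))
  s_out2 <- s
  s_out2$hr[i_trans] <- s_out2$hr[i_trans] + 12
  res2 <- remove_aberrant(s_out2)
  expect_identical(unname(lengths(res2$removed)), rep(0L, 3))
})

test_that("removal threshold scales with the window residual SD", {
  # noisy base: a 6-SD displacement is removed, the residual-SD estimate
  # coming from the oracle fit of the same window
  set.seed(31)
  s <- linear_trial_series()
  s$hr <- s$hr + rnorm(nrow(s), 0, 1)
  w <- which(s$t >= 360)
  fit <- lm(hr ~ t, data = data.frame(t = s$t[w], hr = s$hr[w]))
  sigma <- sqrt(sum(resid(fit)^2) / (length(w) - 2))
  i <- w[60]
  s$hr[i] <- predict(fit)[60] + 6 * sigma
  res <- remove_aberrant(s)
  expect_true(i %in% res$removed$hr)
})

test_that("window shortfall raises an informative error", {
  s <- linear_trial_series(t = seq(100, 720, by = 3))  # no baseline coverage
  expect_error(remove_aberrant(s), "span")
})

test_that("1-s interpolation is linear, exact and idempotent", {
  s <- flat_series(c(0, 4), c(100, 108))
  out <- interpolate_1s(s)
  expect_equal(out$t, 0:4)
  expect_equal(out$hr, c(100, 102, 104, 106, 108))

  reg <- flat_series(0:50, sin(0:50))
  expect_equal(interpolate_1s(reg)$hr, reg$hr)

  # closed-form check: interpolating samples of a line reproduces the line
  set.seed(5)
  t <- sort(c(0, cumsum(runif(100, 0.5, 4))))
  a <- 3.2; b <- -0.7
  s2 <- flat_series(t, a + b * t)
  out2 <- interpolate_1s(s2)
  expect_equal(out2$vo2, a + b * out2$t, tolerance = 1e-12)

  expect_error(interpolate_1s(flat_series(c(0, 3), c(1, NA))), "2 non-missing")
})

test_that("5-s binning averages full windows at their centres", {
  s <- flat_series(0:4, 1:5)
  out <- bin_5s(s)
  expect_equal(out$t, 2)
  expect_equal(out$hr, 3)

  cs <- bin_5s(flat_series(0:59, rep(7, 60)))
  expect_true(all(cs$vo2 == 7))
  expect_equal(cs$t, seq(2, 57, by = 5))

  # conservation of the mean over an equal-size partition
  set.seed(8)
  y <- rnorm(600)
  out3 <- bin_5s(flat_series(0:599, y))
  expect_equal(nrow(out3), 120)
  expect_equal(mean(out3$hr), mean(y), tolerance = 1e-12)

  # median statistic
  out4 <- bin_5s(flat_series(0:4, c(1, 1, 2, 50, 60)), statistic = "median")
  expect_equal(out4$hr, 2)

  expect_error(bin_5s(flat_series(c(0, 2, 4), 1:3)), "regular")
})

test_that("cleaning pipeline leaves the scHR of a noiseless trial unchanged", {
  subj <- fixed_subject()
  sim <- simulate_constant_trial(subj, 2200, seed = 13, noise = zero_noise())
  raw <- compute_schr(sim$series)$schr
  cln <- compute_schr(clean_trial(sim$series))$schr
  expect_lt(abs(raw - cln), 1e-6)
  expect_lt(abs(raw - sim$truth$true_schr), 1e-6)
})

test_that("injected outliers on a line-consistent base are fully removed with
          no false positives", {
  for (seed in 1:5) {
    s <- linear_trial_series()
    inj <- inject_aberrant(s, rate = 0.05, magnitude = 5, seed = seed)
    res <- remove_aberrant(inj$series)
    removed <- sort(unique(unlist(res$removed)))
    expect_true(all(inj$outlier_indices %in% removed))
    expect_identical(setdiff(removed, inj$outlier_indices), integer(0))
    u <- s$t[removed] - 180
    expect_false(any(u > 0 & u < 180))
  }
})

test_that("clean_trial reports per-channel removal counts", {
  subj <- fixed_subject()
  sim <- simulate_constant_trial(subj, 2000, seed = 17)
  cs <- clean_trial(sim$series)
  rc <- removed_counts(cs)
  expect_named(rc, c("vo2", "vco2", "hr"))
  expect_true(all(rc >= 0))
  expect_equal(diff(cs$t), rep(5, nrow(cs) - 1))  # regular 5-s grid, no gaps
})
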