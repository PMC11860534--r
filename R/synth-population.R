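#' Population generator configuration
#'
#' Distributional defaults for the synthetic subject generator. The defaults
#' mimic the development cohort of the scHR study: sex-specific relative
#' V̇O₂max (males 51.0 ± 11.0, females 41.4 ± 7.1 mL·min⁻¹·kg⁻¹), gas exchange
#' threshold at 62.1 ± 7.1 %V̇O₂max and respiratory compensation point at
#' 84.5 ± 6.0 %V̇O₂max, pooled across sexes.
#'
#' @param vo2max_rel_mean,vo2max_rel_sd named vectors (`male`, `female`) of the
#'   relative V̇O₂max distribution, mL·min⁻¹·kg⁻¹.
#' @param get_frac_mean,get_frac_sd gas exchange threshold as a fraction of
#'   V̇O₂max.
#' @param rcp_frac_mean,rcp_frac_sd respiratory compensation point as a
#'   fraction of V̇O₂max.
#' @param body_mass_mean,body_mass_sd named vectors, kg.
#' @param height_mean,height_sd named vectors, cm.
#' @param hr_rest_mean,hr_rest_sd resting heart rate, bpm.
#' @param hrmax_sd residual SD (bpm) around the age-predicted maximum heart
#'   rate 208 − 0.7·age.
#' @param vo2_rest_per_kg,vo2_rest_sd resting V̇O₂ as mL·min⁻¹·kg⁻¹ plus an
#'   additive residual SD in mL·min⁻¹.
#' @param vo2_po_slope_mean,vo2_po_slope_sd gain of the V̇O₂/power relation,
#'   mL·min⁻¹·W⁻¹.
#' @param mrt_mean,mrt_sd mean response time of V̇O₂ to a ramp, s.
#' @param age_range named list of `c(lo, hi)` integer age bounds per age group.
#'
#' @return a list of class `population_config`.
#' @export
population_config <- function(vo2max_rel_mean = c(male = 51.0, female = 41.4),
                              vo2max_rel_sd = c(male = 11.0, female = 7.1),
                              get_frac_mean = 0.621, get_frac_sd = 0.071,
                              rcp_frac_mean = 0.845, rcp_frac_sd = 0.060,
                              body_mass_mean = c(male = 75, female = 62),
                              body_mass_sd = c(male = 9, female = 8),
                              height_mean = c(male = 178, female = 165),
                              height_sd = c(male = 7, female = 6),
                              hr_rest_mean = 62, hr_rest_sd = 8,
                              hrmax_sd = 8,
                              vo2_rest_per_kg = 3.5, vo2_rest_sd = 30,
                              vo2_po_slope_mean = 10.1, vo2_po_slope_sd = 0.8,
                              mrt_mean = 40, mrt_sd = 10,
                              age_range = list(young = c(18, 35),
                                               middle = c(36, 55),
                                               elderly = c(56, 75))) {
  cfg <- list(vo2max_rel_mean = vo2max_rel_mean, vo2max_rel_sd = vo2max_rel_sd,
              get_frac_mean = get_frac_mean, get_frac_sd = get_frac_sd,
              rcp_frac_mean = rcp_frac_mean, rcp_frac_sd = rcp_frac_sd,
              body_mass_mean = body_mass_mean, body_mass_sd = body_mass_sd,
              height_mean = height_mean, height_sd = height_sd,
              hr_rest_mean = hr_rest_mean, hr_rest_sd = hr_rest_sd,
              hrmax_sd = hrmax_sd,
              vo2_rest_per_kg = vo2_rest_per_kg, vo2_rest_sd = vo2_rest_sd,
              vo2_po_slope_mean = vo2_po_slope_mean,
              vo2_po_slope_sd = vo2_po_slope_sd,
              mrt_mean = mrt_mean, mrt_sd = mrt_sd,
              age_range = age_range)
  class(cfg) <- "population_config"
  cfg
}

#' Population configuration mimicking the validation cohort
#'
#' Same machinery as [population_config()] but with moments matching the
#' independent validation sample (relative V̇O₂max ≈ 40.7 mL·min⁻¹·kg⁻¹ in both
#' sexes, GET 61.1 %V̇O₂max, RCP 83.1 %V̇O₂max).
#'
#' @return a `population_config` list.
#' @export
step2_population_config <- function() {
  population_config(vo2max_rel_mean = c(male = 40.6, female = 40.8),
                    vo2max_rel_sd = c(male = 11.1, female = 7.0),
                    get_frac_mean = 0.611, get_frac_sd = 0.085,
                    rcp_frac_mean = 0.831, rcp_frac_sd = 0.060)
}

#' Stratification plans
#'
#' `step1_strata()` reproduces the development-cohort plan (65 subjects:
#' 23 young with 12 females, 22 middle-aged with 12 females, 20 elderly with
#' 10 females). `step2_strata()` reproduces the validation plan (36 subjects,
#' 12 per age group, half female). Proportions are relative; any total `n`
#' is apportioned by largest remainder.
#'
#' @return a tibble with columns `age_group`, `sex`, `prop`.
#' @export
step1_strata <- function() {
  tibble::tibble(
    age_group = rep(c("young", "middle", "elderly"), each = 2L),
    sex = rep(c("female", "male"), times = 3L),
    prop = c(12, 11, 12, 10, 10, 10) / 65)
}

#' @rdname step1_strata
#' @export
step2_strata <- function() {
  tibble::tibble(
    age_group = rep(c("young", "middle", "elderly"), each = 2L),
    sex = rep(c("female", "male"), times = 3L),
    prop = rep(1 / 6, 6L))
}

# Largest-remainder apportionment of n across proportions (deterministic;
# ties resolved by first occurrence).
apportion <- function(n, prop) {
  if (any(!is.finite(prop)) || any(prop < 0) || sum(prop) <= 0)
    stop_hrsc("invalid strata: proportions must be non-negative and sum to a positive value")
  p <- prop / sum(prop)
  quota <- n * p
  k <- floor(quota)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(quota - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

#' Generate a synthetic subject population
#'
#' Draws age/sex-stratified subject profiles with resting and maximal
#' cardiorespiratory parameters and known gas-exchange thresholds. All draws
#' are truncated to physiological invariants (0 < GET < RCP < 1 as fractions
#' of V̇O₂max, resting V̇O₂ below the GET, resting HR below HRmax).
#'
#' @param n number of subjects (≥ 1).
#' @param seed integer seed, or `NULL` to consume the current RNG stream.
#' @param strata stratification plan, see [step1_strata()].
#' @param config distributional configuration, see [population_config()].
#'
#' @return a tibble with one row per subject: `subject_id`, `age_group`,
#'   `age` (yr), `sex`, `body_mass` (kg), `height` (cm), `vo2_rest`,
#'   `vo2max_abs` (mL·min⁻¹), `vo2max_rel` (mL·min⁻¹·kg⁻¹), `hrmax`,
#'   `hr_rest` (bpm), `get_frac`, `rcp_frac` (fractions of V̇O₂max),
#'   `vo2_po_slope` (mL·min⁻¹·W⁻¹), `mrt` (s).
#' @export
generate_population <- function(n, seed = NULL, strata = step1_strata(),
                                config = population_config()) {
  if (!is_scalar_number(n) || n < 1) stop_hrsc("n must be a positive integer")
  n <- as.integer(n)
  counts <- apportion(n, strata$prop)
  local_seed(seed, {
    rows <- vector("list", nrow(strata))
    for (i in seq_len(nrow(strata))) {
      k <- counts[i]
      if (k == 0L) next
      sex <- strata$sex[i]
      grp <- strata$age_group[i]
      rng <- config$age_range[[grp]]
      age <- floor(stats::runif(k, rng[1], rng[2] + 1))
      body_mass <- draw_trunc(k, config$body_mass_mean[[sex]],
                              config$body_mass_sd[[sex]], lo = 40, hi = 130)
      height <- draw_trunc(k, config$height_mean[[sex]],
                           config$height_sd[[sex]], lo = 140, hi = 210)
      vo2max_rel <- draw_trunc(k, config$vo2max_rel_mean[[sex]],
                               config$vo2max_rel_sd[[sex]], lo = 15, hi = 90)
      vo2max_abs <- vo2max_rel * body_mass
      get_frac <- draw_trunc(k, config$get_frac_mean, config$get_frac_sd,
                             lo = 0.35, hi = 0.90)
      rcp_frac <- draw_trunc(k, config$rcp_frac_mean, config$rcp_frac_sd,
                             lo = 0.55, hi = 0.98)
      bad <- which(rcp_frac <= get_frac + 0.03)
      while (length(bad)) {
        get_frac[bad] <- draw_trunc(length(bad), config$get_frac_mean,
                                    config$get_frac_sd, lo = 0.35, hi = 0.90)
        rcp_frac[bad] <- draw_trunc(length(bad), config$rcp_frac_mean,
                                    config$rcp_frac_sd, lo = 0.55, hi = 0.98)
        bad <- bad[rcp_frac[bad] <= get_frac[bad] + 0.03]
      }
      hr_rest <- draw_trunc(k, config$hr_rest_mean, config$hr_rest_sd,
                            lo = 38, hi = 100)
      hrmax <- draw_trunc(k, 208 - 0.7 * age, config$hrmax_sd,
                          lo = hr_rest + 30, hi = 220)
      vo2_rest <- draw_trunc(k, config$vo2_rest_per_kg * body_mass,
                             config$vo2_rest_sd, lo = 120,
                             hi = 0.5 * get_frac * vo2max_abs)
      vo2_po_slope <- draw_trunc(k, config$vo2_po_slope_mean,
                                 config$vo2_po_slope_sd, lo = 7.5, hi = 13)
      mrt <- draw_trunc(k, config$mrt_mean, config$mrt_sd, lo = 10, hi = 90)
      rows[[i]] <- tibble::tibble(
        age_group = grp, age = age, sex = sex,
        body_mass = body_mass, height = height,
        vo2_rest = vo2_rest, vo2max_abs = vo2max_abs, vo2max_rel = vo2max_rel,
        hrmax = hrmax, hr_rest = hr_rest,
        get_frac = get_frac, rcp_frac = rcp_frac,
        vo2_po_slope = vo2_po_slope, mrt = mrt)
    }
    pop <- do.call(rbind, rows)
    pop <- tibble::add_column(pop,
                              subject_id = sprintf("S%03d", seq_len(nrow(pop))),
                              .before = 1L)
    pop
  })
}
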