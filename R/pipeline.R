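#' Pipeline configuration
#'
#' Assembles and validates the configuration of the two-step pipeline. Every
#' field has a documented default; unknown fields are rejected (they would be
#' unused arguments).
#'
#' @param seed integer seed driving every source of randomness.
#' @param n_subjects development-cohort size (Step 1).
#' @param n_subjects_step2 validation-cohort size (Step 2).
#' @param noise a [noise_config()].
#' @param kinetics a [kinetics_config()].
#' @param population,population_step2 [population_config()]s for the two
#'   cohorts.
#' @param strata,strata_step2 stratification plans.
#' @param sd_mult,bin_statistic cleaning parameters.
#' @param fit_start scHR fit start, s after onset.
#' @param alpha_in,r_cut,vif_cut forward-selection parameters.
#' @param sc_gain above-GET slow-component gain for power prescription,
#'   mL·min⁻¹·W⁻¹.
#' @param out_dir output directory for CSV/JSON artifacts, or `NULL` for
#'   in-memory results only.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 65, n_subjects_step2 = 36,
                            noise = noise_config(),
                            kinetics = kinetics_config(),
                            population = population_config(),
                            population_step2 = step2_population_config(),
                            strata = step1_strata(),
                            strata_step2 = step2_strata(),
                            sd_mult = 3, bin_statistic = "mean",
                            fit_start = 300,
                            alpha_in = 0.05, r_cut = 0.70, vif_cut = 5,
                            sc_gain = 0, out_dir = NULL) {
  stopifnot(inherits(noise, "noise_config"),
            inherits(kinetics, "kinetics_config"),
            inherits(population, "population_config"))
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 n_subjects_step2 = n_subjects_step2, noise = noise,
                 kinetics = kinetics, population = population,
                 population_step2 = population_step2, strata = strata,
                 strata_step2 = strata_step2, sd_mult = sd_mult,
                 bin_statistic = bin_statistic, fit_start = fit_start,
                 alpha_in = alpha_in, r_cut = r_cut, vif_cut = vif_cut,
                 sc_gain = sc_gain, out_dir = out_dir),
            class = "pipeline_config")
}

#' Step 1: develop the prediction equation
#'
#' Simulates the development cohort, runs every trial through cleaning and
#' metric extraction, and refits the prediction equation by forward
#' regression. When `config$out_dir` is set, writes the per-trial metrics
#' CSV, the model JSON and a run manifest.
#'
#' @param config a [pipeline_config()].
#' @return a list: `population`, `metrics` (per-trial tibble), `model`
#'   (`schr_model`), `freewheel_cv` (within-subject freewheeling HR CV).
#' @export
run_step1 <- function(config = pipeline_config()) {
  res <- recover_parameters(n_subjects = config$n_subjects,
                            trials_per_subject = 6,
                            sigma_resid = config$noise$sigma_resid,
                            seed = config$seed, noise = config$noise,
                            strata = config$strata,
                            config = config$population,
                            sd_mult = config$sd_mult,
                            statistic = config$bin_statistic,
                            alpha_in = config$alpha_in, r_cut = config$r_cut,
                            vif_cut = config$vif_cut)
  out <- list(population = res$population, metrics = res$data,
              model = res$model)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_population_csv(res$population,
                         file.path(config$out_dir, "population_step1.csv"))
    utils::write.csv(res$data, file.path(config$out_dir, "metrics_step1.csv"),
                     row.names = FALSE, na = "")
    write_model_json(res$model, file.path(config$out_dir, "schr_model.json"))
    write_manifest(config, file.path(config$out_dir, "manifest_step1.json"))
  }
  out
}

#' Step 2: validate the prediction equation
#'
#' Simulates the independent validation cohort (three constant-work trials
#' per subject at 50% of each domain's span, 15/12/9 min for the
#' moderate/heavy/severe domain), projects the end-exercise HR from the
#' fifth-minute HR and the model-predicted scHR, and compares projections to
#' the measured end-exercise HR by Bland–Altman and Pearson analysis. Also
#' reports the within-subject freewheeling HR CV across the three visits.
#'
#' @param config a [pipeline_config()].
#' @param model an `schr_model` used for the projection (default: the
#'   published equation).
#' @return a list: `report` (an `agreement_report`), `pairs` (per-trial
#'   tibble with measured and estimated end HR), `freewheel_cv`,
#'   `population`.
#' @export
run_step2 <- function(config = pipeline_config(),
                      model = published_schr_model()) {
  local_seed(config$seed + 1L, {
    pop <- generate_population(config$n_subjects_step2, seed = NULL,
                               strata = config$strata_step2,
                               config = config$population_step2)
    rows <- vector("list", nrow(pop) * 3L)
    fw <- vector("list", nrow(pop))
    k <- 0L
    for (i in seq_len(nrow(pop))) {
      subj <- pop[i, ]
      plan <- prescribe_trials(subj, step = 2, sc_gain = config$sc_gain)
      fw_hr <- numeric(nrow(plan))
      for (j in seq_len(nrow(plan))) {
        sim <- simulate_constant_trial(subj, plan$target_vo2[j],
                                       duration = plan$duration[j],
                                       seed = NULL, noise = config$noise,
                                       kinetics = config$kinetics)
        cs <- clean_trial(sim$series, sd_mult = config$sd_mult,
                          statistic = config$bin_statistic)
        # freewheeling HR: mean over the last 2 min of the 3-min baseline
        bw <- which(cs$t >= 60 & cs$t <= 180)
        fw_hr[j] <- mean(cs$hr[bw])
        t_end_min <- plan$duration[j] / 60
        hr_5 <- window_value(cs, "hr", 5)
        vo2_5 <- window_value(cs, "vo2", 5)
        # measured end HR: mean over the last minute of exercise; the window
        # mean represents its temporal centre, so the projection targets that
        # centre (the same centre convention as the 5-s bins)
        hr_end <- mean(cs$hr[cs$t >= 180 + plan$duration[j] - 60 - 1e-9 &
                               cs$t <= 180 + plan$duration[j] + 1e-9])
        t_proj <- t_end_min - 0.5
        p_rcp <- pct_rcp(vo2_5, subj$rcp_frac * subj$vo2max_abs)
        schr_hat <- eval_schr_model(model, list(
          pct_rcp = p_rcp, age = subj$age,
          sex_female = sex_to_flag(subj$sex), hrmax = subj$hrmax,
          vo2_5min = vo2_5, vo2max_rel = subj$vo2max_rel))
        hr_est <- project_hr(hr_5, schr_hat, t_proj)
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          subject_id = subj$subject_id, trial_label = plan$trial_label[j],
          domain = plan$domain[j], t_end_min = t_end_min,
          hr_5min = hr_5, pct_rcp = p_rcp, schr_est = schr_hat,
          hr_measured_end = hr_end, hr_estimated_end = hr_est,
          true_schr = sim$truth$true_schr)
      }
      fw[[i]] <- fw_hr
    }
    pairs <- do.call(rbind, rows)
    report <- bland_altman(pairs$hr_measured_end, pairs$hr_estimated_end)
    cv <- within_subject_cv(fw)
    out <- list(report = report, pairs = pairs, freewheel_cv = cv,
                population = pop)
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_population_csv(pop,
                           file.path(config$out_dir, "population_step2.csv"))
      utils::write.csv(pairs, file.path(config$out_dir, "pairs_step2.csv"),
                       row.names = FALSE, na = "")
      write_report_json(report,
                        file.path(config$out_dir, "agreement_report.json"))
      write_manifest(config, file.path(config$out_dir, "manifest_step2.json"))
    }
    out
  })
}
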