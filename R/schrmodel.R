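#' The published scHR prediction equation
#'
#' Linear model predicting the heart-rate slow component (bpm·min⁻¹) from the
#' relative exercise intensity to the respiratory compensation point, age and
#' sex:
#'
#' scHR = −0.0514 + 0.0240·%RCP − 0.0172·age − 0.347·sex
#'
#' with sex coded male = 0, female = 1; r² = 0.53 and a standard error of
#' estimate of 0.61 bpm·min⁻¹ in the development cohort.
#'
#' @return an object of class `schr_model` holding the published
#'   coefficients and fit diagnostics.
#' @export
published_schr_model <- function() {
  new_schr_model(
    coefficients = c(`(Intercept)` = -0.0514, pct_rcp = 0.0240,
                     age = -0.0172, sex_female = -0.347),
    se = NULL, r2 = 0.53, see = 0.61, n_obs = NA_integer_,
    df_residual = NA_integer_,
    selected_predictors = c("pct_rcp", "age", "sex_female"))
}

new_schr_model <- function(coefficients, se, r2, see, n_obs, df_residual,
                           selected_predictors) {
  structure(list(coefficients = coefficients, se = se, r2 = r2, see = see,
                 n_obs = n_obs, df_residual = df_residual,
                 selected_predictors = selected_predictors),
            class = "schr_model")
}

#' @export
print.schr_model <- function(x, ...) {
  cat("scHR linear model\n")
  cat("  coefficients:\n")
  for (nm in names(x$coefficients))
    cat(sprintf("    %-12s %10.4f\n", nm, x$coefficients[[nm]]))
  cat(sprintf("  r2 = %s, SEE = %s bpm/min, n = %s\n",
              format(x$r2), format(x$see),
              ifelse(is.na(x$n_obs), "NA", x$n_obs)))
  invisible(x)
}

#' @export
coef.schr_model <- function(object, ...) object$coefficients

#' @export
confint.schr_model <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$se))
    stop_hrsc("model carries no standard errors (published constant?)")
  est <- object$coefficients
  if (missing(parm)) parm <- names(est)
  q <- stats::qt(1 - (1 - level) / 2, object$df_residual)
  out <- cbind(est[parm] - q * object$se[parm],
               est[parm] + q * object$se[parm])
  colnames(out) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                trim = TRUE), "%")
  out
}

sex_to_flag <- function(sex) {
  if (is.numeric(sex)) {
    if (any(!sex %in% c(0, 1))) stop_hrsc("numeric sex must be 0 (male) or 1 (female)")
    return(as.numeric(sex))
  }
  s <- tolower(as.character(sex))
  if (any(!s %in% c("male", "female")))
    stop_hrsc("unknown sex label; use \"male\" or \"female\"")
  as.numeric(s == "female")
}

#' Predict the heart-rate slow component
#'
#' Evaluates an scHR linear model (by default the published equation) at the
#' given relative intensity, age and sex. The prediction may be negative and
#' is returned as-is; truncation is the caller's policy.
#'
#' @param pct_rcp relative exercise intensity to the RCP, percent (> 0; 0 is
#'   allowed for evaluating the intercept).
#' @param age age in years (≥ 0).
#' @param sex `"male"`/`"female"` (or 0/1 with female = 1).
#' @param model an `schr_model` whose predictors are a subset of
#'   `pct_rcp`, `age`, `sex_female`.
#' @return predicted scHR, bpm·min⁻¹ (vectorised).
#' @export
predict_schr <- function(pct_rcp, age, sex, model = published_schr_model()) {
  if (any(pct_rcp < 0)) stop_hrsc("pct_rcp must be non-negative")
  if (any(age < 0)) stop_hrsc("age must be non-negative")
  cf <- model$coefficients
  known <- c("(Intercept)", "pct_rcp", "age", "sex_female")
  if (any(!names(cf) %in% known))
    stop_hrsc("model contains predictors predict_schr cannot evaluate: ",
              paste(setdiff(names(cf), known), collapse = ", "))
  get_cf <- function(nm) if (nm %in% names(cf)) cf[[nm]] else 0
  get_cf("(Intercept)") + get_cf("pct_rcp") * pct_rcp +
    get_cf("age") * age + get_cf("sex_female") * sex_to_flag(sex)
}

# Evaluate an arbitrary fitted scHR model on a named list/one-row frame of
# predictor values (internal; predict_schr keeps the three-predictor surface).
eval_schr_model <- function(model, values) {
  cf <- model$coefficients
  out <- if ("(Intercept)" %in% names(cf)) cf[["(Intercept)"]] else 0
  for (nm in setdiff(names(cf), "(Intercept)")) {
    if (is.null(values[[nm]]))
      stop_hrsc("no value supplied for model predictor ", nm)
    out <- out + cf[[nm]] * values[[nm]]
  }
  out
}

partial_f_p <- function(data, response, included, candidate) {
  f0 <- stats::lm(stats::reformulate(if (length(included)) included else "1",
                                     response), data = data)
  f1 <- stats::lm(stats::reformulate(c(included, candidate), response),
                  data = data)
  rss0 <- sum(stats::resid(f0)^2)
  rss1 <- sum(stats::resid(f1)^2)
  df1 <- f1$df.residual
  if (df1 <= 0 || rss1 <= 0) return(0)
  Fst <- (rss0 - rss1) / (rss1 / df1)
  stats::pf(Fst, 1, df1, lower.tail = FALSE)
}

# Sequentially screen an entry-ordered predictor set for collinearity: a
# violation is an absolute pairwise Pearson correlation above r_cut, or a VIF
# against the retained set above vif_cut. From each violating pair, the
# member whose removal least reduces the model's explanatory power (lower
# residual sum of squares when the other is kept) is retained — entry order
# alone does not decide, because a collinear proxy can enter one step before
# the predictor it shadows.
screen_collinear <- function(data, response, entry_order, r_cut, vif_cut) {
  rss_with <- function(preds) {
    sum(stats::resid(stats::lm(stats::reformulate(preds, response),
                               data = data))^2)
  }
  keep <- entry_order[1]
  dropped <- character(0)
  for (nm in entry_order[-1]) {
    partner <- NULL
    rmax <- 0
    for (k in keep) {
      r <- abs(stats::cor(data[[nm]], data[[k]]))
      if (r > r_cut && r > rmax) {
        partner <- k
        rmax <- r
      }
    }
    if (is.null(partner) && length(keep) >= 1) {
      r2 <- summary(stats::lm(stats::reformulate(keep, nm),
                              data = data))$r.squared
      if (r2 < 1 && 1 / (1 - r2) > vif_cut) {
        cors <- vapply(keep, function(k) abs(stats::cor(data[[nm]], data[[k]])),
                       numeric(1))
        partner <- keep[which.max(cors)]
      }
    }
    if (is.null(partner)) {
      keep <- c(keep, nm)
    } else if (rss_with(c(setdiff(keep, partner), nm)) <
                 rss_with(keep)) {
      dropped <- c(dropped, partner)
      keep <- c(setdiff(keep, partner), nm)
    } else {
      dropped <- c(dropped, nm)
    }
  }
  dropped
}

#' Forward multiple regression with collinearity screening
#'
#' Builds an scHR prediction model by forward selection: at each step the
#' candidate with the smallest partial-F p-value below `alpha_in` is added;
#' after each addition, pairwise Pearson correlations and variance inflation
#' factors among the included predictors are checked. From each pair
#' violating `r_cut` or `vif_cut`, the member whose removal least reduces the
#' model's explanatory power is retained and the other is discarded from the
#' model and from further candidacy. Selection stops when
#' no candidate qualifies (or the fit is numerically perfect). The final
#' model is an ordinary least-squares fit on the surviving set, with the
#' standard error of estimate using the n − p − 1 denominator.
#'
#' @param data a data frame containing the response and candidate columns.
#' @param response response column name (default `"schr"`).
#' @param candidates candidate predictor column names; default all remaining
#'   numeric columns.
#' @param alpha_in entry threshold on the partial-F p-value.
#' @param r_cut pairwise correlation screening threshold.
#' @param vif_cut variance-inflation screening threshold.
#' @return an `schr_model` with coefficients, standard errors, r², SEE,
#'   `n_obs` and the entry-ordered `selected_predictors`.
#' @export
forward_select <- function(data, response = "schr", candidates = NULL,
                           alpha_in = 0.05, r_cut = 0.70, vif_cut = 5) {
  data <- as.data.frame(data)
  candidates <- candidates %||%
    setdiff(names(data)[vapply(data, is.numeric, logical(1))], response)
  if (nrow(data) < 10 * length(candidates))
    stop_hrsc("need at least 10 observations per candidate predictor")
  y <- data[[response]]
  sst <- sum((y - mean(y))^2)
  included <- character(0)
  pool <- candidates
  repeat {
    if (!length(pool)) break
    f0 <- stats::lm(stats::reformulate(if (length(included)) included else "1",
                                       response), data = data)
    rss0 <- sum(stats::resid(f0)^2)
    if (rss0 <= 1e-10 * sst) break  # numerically perfect fit
    pv <- vapply(pool, function(cand) {
      partial_f_p(data, response, included, cand)
    }, numeric(1))
    j <- which.min(pv)
    if (!is.finite(pv[j]) || pv[j] >= alpha_in) break
    included <- c(included, pool[j])
    pool <- setdiff(pool, pool[j])
    if (length(included) >= 2L) {
      drop <- screen_collinear(data, response, included, r_cut, vif_cut)
      included <- setdiff(included, drop)
      pool <- setdiff(pool, drop)
    }
  }
  fit <- stats::lm(stats::reformulate(if (length(included)) included else "1",
                                      response), data = data)
  cf <- stats::coef(fit)
  if (any(is.na(cf)))
    stop_hrsc("rank-deficient design; collinear columns: ",
              paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)
  new_schr_model(coefficients = cf,
                 se = sm$coefficients[, "Std. Error"],
                 r2 = sm$r.squared,
                 see = sm$sigma,
                 n_obs = nrow(data),
                 df_residual = fit$df.residual,
                 selected_predictors = included)
}

#' End-to-end parameter recovery harness
#'
#' Generates a stratified population, prescribes the six domain-anchored
#' constant-work trials per subject, simulates each trial (true slope drawn
#' from the published equation plus a Normal(0, `sigma_resid`) residual),
#' cleans the breath-by-breath data, estimates each trial's scHR and
#' fifth-minute metrics, and refits the prediction equation by forward
#' regression over the candidate set used in the original analysis (%RCP,
#' age, sex, HRmax, fifth-minute V̇O₂, relative V̇O₂max).
#'
#' @param n_subjects number of subjects (≥ 20).
#' @param trials_per_subject 1–6 trials per subject, taken in the anchor
#'   order M1, H1, S1, M2, H2, S2 so smaller designs still span the domains.
#' @param sigma_resid residual SD of the generated slope, bpm·min⁻¹.
#' @param seed integer seed or `NULL`.
#' @param noise a [noise_config()]; its `sigma_resid` is overridden by the
#'   `sigma_resid` argument.
#' @param strata,config population plan and distributions.
#' @param sd_mult,statistic cleaning parameters, see [clean_trial()].
#' @param alpha_in,r_cut,vif_cut selection parameters, see
#'   [forward_select()].
#' @return a list: `model` (fitted `schr_model`), `data` (per-trial table),
#'   `generating` (the generating coefficients, i.e. the published model),
#'   `population`.
#' @export
recover_parameters <- function(n_subjects = 65, trials_per_subject = 6,
                               sigma_resid = 0.61, seed = NULL,
                               noise = noise_config(),
                               strata = step1_strata(),
                               config = population_config(),
                               sd_mult = 3, statistic = "mean",
                               alpha_in = 0.05, r_cut = 0.70, vif_cut = 5) {
  if (!is_scalar_number(n_subjects) || n_subjects < 20)
    stop_hrsc("n_subjects must be at least 20")
  if (!is_scalar_number(trials_per_subject) || trials_per_subject < 1 ||
      trials_per_subject > 6)
    stop_hrsc("trials_per_subject must be between 1 and 6")
  noise$sigma_resid <- sigma_resid
  anchor_order <- c(1L, 3L, 5L, 2L, 4L, 6L)[seq_len(trials_per_subject)]
  local_seed(seed, {
    pop <- generate_population(n_subjects, seed = NULL, strata = strata,
                               config = config)
    nr <- n_subjects * trials_per_subject
    col <- function(init) rep(init, nr)
    dat <- list(subject_id = col(NA_character_),
                trial_label = col(NA_character_), schr = col(NA_real_),
                pct_rcp = col(NA_real_), age = col(NA_real_),
                sex_female = col(NA_real_), hrmax = col(NA_real_),
                vo2_5min = col(NA_real_), vo2max_rel = col(NA_real_),
                true_schr = col(NA_real_))
    k <- 0L
    for (i in seq_len(n_subjects)) {
      subj <- pop[i, ]
      plan <- prescribe_trials(subj, step = 1)[anchor_order, ]
      sexf <- sex_to_flag(subj$sex)
      for (j in seq_len(nrow(plan))) {
        sim <- simulate_constant_trial(subj, plan$target_vo2[j],
                                       duration = plan$duration[j],
                                       seed = NULL, noise = noise)
        cs <- clean_trial(sim$series, sd_mult = sd_mult,
                          statistic = statistic)
        m <- trial_metrics(cs, subj, trial_label = plan$trial_label[j])
        k <- k + 1L
        dat$subject_id[k] <- subj$subject_id
        dat$trial_label[k] <- plan$trial_label[j]
        dat$schr[k] <- m$schr
        dat$pct_rcp[k] <- m$pct_rcp
        dat$age[k] <- subj$age
        dat$sex_female[k] <- sexf
        dat$hrmax[k] <- subj$hrmax
        dat$vo2_5min[k] <- m$vo2_5min
        dat$vo2max_rel[k] <- subj$vo2max_rel
        dat$true_schr[k] <- sim$truth$true_schr
      }
    }
    dat <- tibble::new_tibble(dat, nrow = nr)
    model <- forward_select(dat, response = "schr",
                            candidates = c("pct_rcp", "age", "sex_female",
                                           "hrmax", "vo2_5min", "vo2max_rel"),
                            alpha_in = alpha_in, r_cut = r_cut,
                            vif_cut = vif_cut)
    list(model = model, data = dat,
         generating = published_schr_model(), population = pop)
  })
}
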