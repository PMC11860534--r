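# Readers and writers for the pipeline's plain-text artifacts. The breath CSV
# dialect is: columns t_sec, vo2_mlmin, vco2_mlmin, hr_bpm, po_w; UTF-8 with a
# header row; missing values as empty fields.

#' Breath-series CSV input/output
#'
#' @param series a [breath_series()] (or clean series with the same columns).
#' @param path file path.
#' @return `write_breath_csv` returns `path` invisibly; `read_breath_csv`
#'   returns a [breath_series()].
#' @export
write_breath_csv <- function(series, path) {
  df <- data.frame(t_sec = series$t, vo2_mlmin = series$vo2,
                   vco2_mlmin = series$vco2, hr_bpm = series$hr,
                   po_w = series$po)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_breath_csv
#' @export
read_breath_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "")
  need <- c("t_sec", "vo2_mlmin", "vco2_mlmin", "hr_bpm", "po_w")
  if (!all(need %in% names(df)))
    stop_hrsc("not a breath CSV: expected columns ",
              paste(need, collapse = ", "))
  breath_series(df$t_sec, df$vo2_mlmin, df$vco2_mlmin, df$hr_bpm, df$po_w)
}

#' Population CSV input/output
#'
#' One row per subject; sex is stored as the text labels "male"/"female"
#' (never as silent integer codes).
#'
#' @param population a population tibble from [generate_population()].
#' @param path file path.
#' @export
write_population_csv <- function(population, path) {
  utils::write.csv(as.data.frame(population), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, na.strings = "",
                                    stringsAsFactors = FALSE))
}

#' Trial-truth sidecar CSV
#'
#' Ground-truth ledger for generated trials, keyed by subject and trial
#' label.
#'
#' @param truths a data frame / tibble with at least `subject_id`,
#'   `trial_label` and the truth fields (e.g. `true_schr`).
#' @param path file path.
#' @export
write_truth_csv <- function(truths, path) {
  utils::write.csv(as.data.frame(truths), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, na.strings = "",
                                    stringsAsFactors = FALSE))
}

#' Model JSON input/output
#'
#' @param model an `schr_model`.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  x <- list(coefficients = as.list(model$coefficients),
            se = if (is.null(model$se)) NULL else as.list(model$se),
            r2 = model$r2, see = model$see, n_obs = model$n_obs,
            df_residual = model$df_residual,
            selected_predictors = as.list(model$selected_predictors))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_schr_model(coefficients = unlist(x$coefficients),
                 se = if (length(x$se)) unlist(x$se) else NULL,
                 r2 = x$r2, see = x$see,
                 n_obs = x$n_obs %||% NA_integer_,
                 df_residual = x$df_residual %||% NA_integer_,
                 selected_predictors = unlist(x$selected_predictors))
}

#' Agreement-report JSON input/output
#'
#' @param report an `agreement_report`.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "agreement_report")
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline run bit-identically:
#' the full configuration (noise, kinetics, population, cleaning and
#' selection parameters), the seed and the package and R versions.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_manifest <- function(config, path) {
  x <- list(package = "hrsc",
            package_version = as.character(utils::packageVersion("hrsc")),
            r_version = R.version.string,
            seed = config$seed,
            config = rapply(unclass(config), unclass, how = "replace"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
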