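#' Project the heart rate to the end of exercise
#'
#' Dynamic HR-target adjustment: beyond the fifth minute the HR target is
#' updated at the predicted slow-component rate,
#' `HR@end = HR@5min + scHR × (time − 5)` with time in minutes from exercise
#' onset.
#'
#' @param hr_5min heart rate at the fifth minute, bpm.
#' @param schr slow-component slope, bpm·min⁻¹.
#' @param t_end end-of-exercise time, minutes from onset (≥ 5).
#' @return projected heart rate, bpm (vectorised).
#' @export
project_hr <- function(hr_5min, schr, t_end) {
  if (any(t_end < 5)) stop_hrsc("t_end must be at least 5 minutes")
  hr_5min + schr * (t_end - 5)
}

#' Bland–Altman agreement between measured and estimated heart rates
#'
#' Differences are oriented measured − estimated, so a positive bias means
#' the projection under-predicts. Limits of agreement are
#' `bias ± 1.96 × SD(differences)` (sample SD, n − 1); the z-score is
#' `bias / SD(differences)` (0 when the SD is 0); `pearson_r2` is the squared
#' Pearson correlation of the two lists.
#'
#' @param measured,estimated equal-length numeric vectors (n ≥ 3), bpm.
#' @return an object of class `agreement_report` with fields `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `z_score`, `pearson_r2`, `n_pairs`.
#' @export
bland_altman <- function(measured, estimated) {
  if (length(measured) != length(estimated))
    stop_hrsc("measured and estimated must have the same length")
  if (length(measured) < 3L) stop_hrsc("need at least 3 pairs")
  d <- measured - estimated
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  r2 <- if (stats::sd(measured) > 0 && stats::sd(estimated) > 0) {
    stats::cor(measured, estimated)^2
  } else if (sd_diff == 0) 1 else NA_real_
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 z_score = if (sd_diff > 0) bias / sd_diff else 0,
                 pearson_r2 = r2,
                 n_pairs = length(d)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Bland-Altman agreement (measured - estimated)\n")
  cat(sprintf("  bias     %8.3f bpm (z = %.3f)\n", x$bias, x$z_score))
  cat(sprintf("  SD       %8.3f bpm\n", x$sd_diff))
  cat(sprintf("  LoA      [%.3f, %.3f] bpm\n", x$loa_low, x$loa_high))
  cat(sprintf("  r2       %8.4f   (n = %d pairs)\n", x$pearson_r2, x$n_pairs))
  invisible(x)
}

#' Within-subject coefficient of variation
#'
#' Per subject, 100 × SD/mean across replicate measurements (e.g. the
#' freewheeling HR of repeated visits); summarised as mean ± SD across
#' subjects.
#'
#' @param replicates a list of numeric vectors, one per subject, each with at
#'   least 2 replicates and a positive mean.
#' @return a list: `cv` (per-subject CV, %), `mean`, `sd`.
#' @export
within_subject_cv <- function(replicates) {
  if (!is.list(replicates) || !length(replicates))
    stop_hrsc("replicates must be a non-empty list of numeric vectors")
  cv <- vapply(replicates, function(x) {
    if (length(x) < 2L) stop_hrsc("each subject needs at least 2 replicates")
    m <- mean(x)
    if (m == 0) stop_hrsc("zero mean replicate set")
    100 * stats::sd(x) / m
  }, numeric(1))
  list(cv = cv, mean = mean(cv), sd = stats::sd(cv))
}

#' Bland–Altman plot
#'
#' @param measured,estimated paired heart rates, bpm.
#' @return a ggplot object: per-pair mean vs difference with bias and limits
#'   of agreement.
#' @export
plot_bland_altman <- function(measured, estimated) {
  rep <- bland_altman(measured, estimated)
  df <- tibble::tibble(avg = (measured + estimated) / 2,
                       diff = measured - estimated)
  ggplot2::ggplot(df, ggplot2::aes(x = avg, y = diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = rep$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(rep$loa_low, rep$loa_high),
                        linetype = 2) +
    ggplot2::labs(x = "Mean of measured and estimated HR (bpm)",
                  y = "Measured - estimated HR (bpm)") +
    ggplot2::theme_minimal()
}
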