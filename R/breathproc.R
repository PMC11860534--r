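#' Remove aberrant breath-by-breath data points
#'
#' Per channel, two ordinary-least-squares lines are fitted: one over the
#' baseline window (`onset − 180` to `onset`) and one over the steady-state
#' window (`onset + 180` to the end of the trial). Within each window, points
#' whose absolute residual exceeds `sd_mult` times the window fit's residual
#' standard error (n − 2 denominator) are removed. Points in the early
#' transition — `t` in `(onset, onset + 180)` — are never removed. Fitting is
#' single-pass: windows are not refitted after removal.
#'
#' Removal is per-channel and independent: a breath flagged in HR is not
#' removed from V̇O₂. Removed values are set to `NA` in the returned series.
#'
#' @param series a [breath_series()] (or any tibble with `t` and the channels).
#' @param onset exercise onset time, s. The series must span at least
#'   `[onset − 180, onset + 240]`.
#' @param sd_mult removal threshold in residual SDs (default 3).
#' @param channels channels to clean.
#'
#' @return a list with `series` (cleaned copy, removals as `NA`) and
#'   `removed`, a named list of removed sample indices per channel.
#' @export
remove_aberrant <- function(series, onset = 180, sd_mult = 3,
                            channels = c("vo2", "vco2", "hr")) {
  t <- series$t
  if (min(t) > onset - 180 + 1e-9 || max(t) < onset + 240 - 1e-9)
    stop_hrsc("series must span at least [onset - 180, onset + 240] s")
  windows <- list(
    baseline = which(t >= onset - 180 - 1e-9 & t <= onset + 1e-9),
    `steady-state` = which(t >= onset + 180 - 1e-9))
  out <- series
  removed <- stats::setNames(vector("list", length(channels)), channels)
  for (ch in channels) {
    y <- series[[ch]]
    rem <- integer(0)
    for (wname in names(windows)) {
      w <- windows[[wname]]
      w <- w[!is.na(y[w])]
      if (length(w) < 4L)
        stop_hrsc(sprintf("fewer than 4 points in the %s fitting window (channel %s)",
                          wname, ch))
      fit <- ols_line(t[w], y[w])
      if (fit$sigma > 0) {
        rem <- c(rem, w[abs(fit$resid) > sd_mult * fit$sigma])
      }
    }
    rem <- sort(unique(rem))
    out[[ch]][rem] <- NA_real_
    removed[[ch]] <- rem
  }
  list(series = out, removed = removed)
}

#' Linearly interpolate a breath series onto a 1-s grid
#'
#' Each channel is interpolated linearly between its non-missing samples onto
#' every integer second in `[ceil(t_first), floor(t_last)]`. Source values
#' falling on integer seconds are preserved exactly; beyond a channel's first
#' or last non-missing sample the nearest value is carried (relevant only when
#' edge samples were removed as aberrant).
#'
#' @param series a [breath_series()], possibly with `NA`s from
#'   [remove_aberrant()].
#' @param channels channels to interpolate.
#' @return a [breath_series()] on the regular 1-s grid.
#' @export
interpolate_1s <- function(series, channels = c("vo2", "vco2", "hr", "po")) {
  t <- series$t
  grid <- seq(ceiling(min(t)), floor(max(t)), by = 1)
  vals <- list()
  for (ch in channels) {
    y <- series[[ch]]
    ok <- !is.na(y)
    if (sum(ok) < 2L)
      stop_hrsc(sprintf("channel %s has fewer than 2 non-missing samples", ch))
    vals[[ch]] <- stats::approx(t[ok], y[ok], xout = grid, method = "linear",
                                rule = 2)$y
  }
  out <- breath_series(grid, vals$vo2, vals$vco2, vals$hr, vals$po)
  attr(out, "meta") <- attr(series, "meta")
  out
}

#' Average a 1-s series into 5-s bins
#'
#' Non-overlapping windows `[5k, 5k + 5)` are reduced with the chosen
#' statistic (mean by default, median optionally) and timestamped at the
#' window centre (`5k + 2` s on the integer grid). Partial windows at either
#' end are dropped.
#'
#' @param series a regular 1-s series from [interpolate_1s()].
#' @param statistic `"mean"` or `"median"`.
#' @param channels channels to bin.
#' @return a tibble of class `clean_series` on a regular 5-s grid.
#' @export
bin_5s <- function(series, statistic = c("mean", "median"),
                   channels = c("vo2", "vco2", "hr", "po")) {
  statistic <- match.arg(statistic)
  t <- series$t
  if (length(t) < 2L || any(abs(diff(t) - 1) > 1e-8))
    stop_hrsc("bin_5s requires a regular 1-s input grid")
  # the 1-s grid is integer-valued, so complete [5k, 5k+5) windows are
  # contiguous runs of 5 samples starting at a multiple of 5
  k0 <- ceiling(t[1] / 5)
  i0 <- 5 * k0 - t[1] + 1
  n_bins <- ((length(t) - i0 + 1) %/% 5)
  if (n_bins < 1L) stop_hrsc("input too short for a single complete 5-s bin")
  idx <- seq.int(i0, i0 + 5L * n_bins - 1L)
  cols <- list(t = (k0 + seq_len(n_bins) - 1) * 5 + 2)
  for (ch in channels) {
    m <- matrix(series[[ch]][idx], nrow = 5L)
    cols[[ch]] <- if (statistic == "mean") {
      .colMeans(m, 5L, n_bins)
    } else {
      apply(m, 2L, stats::median)
    }
  }
  out <- tibble::new_tibble(cols, nrow = n_bins)
  class(out) <- c("clean_series", class(out))
  attr(out, "meta") <- attr(series, "meta")
  out
}

#' Full breath-by-breath cleaning pipeline
#'
#' Applies the three cleaning stages in order: prediction-band outlier
#' removal ([remove_aberrant()]), 1-s linear interpolation
#' ([interpolate_1s()]) and 5-s binning ([bin_5s()]).
#'
#' @inheritParams remove_aberrant
#' @inheritParams bin_5s
#' @return a `clean_series` tibble with attributes `removed` (per-channel
#'   removed indices), `removed_count` (named integer vector) and `onset`.
#' @export
clean_trial <- function(series, onset = 180, sd_mult = 3,
                        statistic = c("mean", "median")) {
  ra <- remove_aberrant(series, onset = onset, sd_mult = sd_mult)
  cs <- bin_5s(interpolate_1s(ra$series), statistic = statistic)
  attr(cs, "removed") <- ra$removed
  attr(cs, "removed_count") <- vapply(ra$removed, length, integer(1))
  attr(cs, "onset") <- onset
  cs
}

#' @rdname clean_trial
#' @param x a `clean_series`.
#' @export
removed_counts <- function(x) attr(x, "removed_count")
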