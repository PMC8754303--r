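#' Percentage of groups moving
#'
#' Per bin, the fraction of tubes/cages with at least one count, smoothed
#' with a centered moving average. Scale-free in counts.
#'
#' @param series An `activity_series`.
#' @param window_min Smoothing window (min); 0 or 1 disables smoothing.
#' @return data.frame `zt_h`, `fraction` (in `[0, 1]`).
#' @export
percent_moving <- function(series, window_min = 5) {
  stopifnot(inherits(series, "activity_series"))
  frac <- rowMeans(series$counts > 0)
  w <- max(1L, round(window_min / series$bin_min))
  data.frame(zt_h = series$zt_h, fraction = moving_average(frac, w))
}

#' Daily peak activity times
#'
#' Per nominal 24-h day, the time of highest activity from low-pass
#' filtered raw data: counts (summed over tubes) are smoothed with a
#' centered moving average of width `cutoff_min` (default just over
#' 30 min) and the argmax within each day is reported; ties are broken by
#' the earliest time. Under free-running conditions the drift of the bout
#' appears as a day-by-day advance of the peak.
#'
#' @param series An `activity_series`.
#' @param cutoff_min Low-pass moving-average width (min); realized as the
#'   nearest odd number of bins.
#' @return data.frame `day`, `peak_zt_h` (in `[0, 24)`).
#' @export
peak_activity_time <- function(series, cutoff_min = 31) {
  stopifnot(inherits(series, "activity_series"))
  x <- rowSums(series$counts)
  w <- max(1L, round(cutoff_min / series$bin_min))
  sm <- moving_average(x, w)
  day <- floor(series$zt_h / 24)
  out <- lapply(sort(unique(day)), function(d) {
    sel <- which(day == d)
    pk <- sel[which.max(sm[sel])]  # which.max returns the first maximum
    data.frame(day = d + 1L, peak_zt_h = series$zt_h[pk] %% 24)
  })
  do.call(rbind, out)
}

#' Chi-square periodogram (Sokolove-Bushell)
#'
#' For each candidate period `P` the time axis is folded modulo `P` into
#' phase classes and the statistic
#' `Qp = N * sum_h (M_h - M)^2 / sum_i (x_i - M)^2`
#' is computed, where `M_h` are phase-class means over the `K` classes and
#' `N` the number of points; under the null of no rhythm `Qp ~ chi-square`
#' with `K - 1` degrees of freedom. The estimated period is the argmax of
#' `Qp` among candidates exceeding their significance line (alpha with
#' Bonferroni correction over the scan); if no candidate is significant
#' the estimate is `NA`.
#'
#' @param series An `activity_series` (tubes are summed).
#' @param p_min_h,p_max_h,step_h Scan range and step (h).
#' @param fold_bin_min Width of the folding phase classes (min).
#' @param alpha Significance level before Bonferroni correction.
#' @return List of class `period_estimate`: `period_h` (NA if nothing
#'   significant), `curve` (data.frame `period_h`, `qp`, `sig_line`),
#'   `alpha`.
#' @export
chi_square_periodogram <- function(series, p_min_h = 16, p_max_h = 32,
                                   step_h = 0.1, fold_bin_min = 10,
                                   alpha = 0.05) {
  stopifnot(inherits(series, "activity_series"))
  x <- rowSums(series$counts)
  t_min <- series$zt_h * 60
  total_h <- (max(t_min) - min(t_min)) / 60
  if (total_h < 2 * p_max_h)
    stop_invalid("series (%.1f h) shorter than 2 x p_max (%g h)",
                 total_h, p_max_h)
  periods <- seq(p_min_h, p_max_h, by = step_h)
  m_all <- mean(x)
  ss_tot <- sum((x - m_all)^2)
  n <- length(x)
  qp <- numeric(length(periods)); sig <- numeric(length(periods))
  n_scan <- length(periods)
  for (i in seq_along(periods)) {
    p_min_units <- periods[i] * 60
    k <- max(2L, round(p_min_units / fold_bin_min))
    cls <- floor(((t_min %% p_min_units) / p_min_units) * k) + 1L
    sh <- as.numeric(rowsum(x, cls))          # class sums, empty dropped
    nh <- tabulate(cls, nbins = k)
    nh <- nh[nh > 0]
    mh <- sh / nh
    qp[i] <- sum(nh * (mh - m_all)^2) / (ss_tot / n)
    sig[i] <- qchisq(1 - alpha / n_scan, df = k - 1L)
  }
  above <- qp > sig
  period_h <- if (any(above)) periods[which.max(qp * above)] else NA_real_
  structure(list(period_h = period_h,
                 curve = data.frame(period_h = periods, qp = qp,
                                    sig_line = sig),
                 alpha = alpha),
            class = "period_estimate")
}

#' Flyby-rate activity series
#'
#' Converts an event table into an acoustic activity measure: event counts
#' per minute, running-averaged over a window (5 min in the cage
#' analyses).
#'
#' @param events Event table as from [run_pipeline()] (`zt_h` column
#'   used).
#' @param window_min Running-average window (min).
#' @param zt_range Range of ZT hours covered by the recording (defaults to
#'   the span of the events, or 0-24 for an empty table).
#' @return data.frame `zt_h`, `events_per_min`.
#' @export
flyby_activity <- function(events, window_min = 5, zt_range = NULL) {
  if (is.null(zt_range)) {
    zt_range <- if (nrow(events)) range(events$zt_h) else c(0, 24)
  }
  breaks <- seq(zt_range[1], zt_range[2] + 1 / 60, by = 1 / 60)
  counts <- if (nrow(events)) {
    as.numeric(table(cut(events$zt_h, breaks, right = FALSE)))
  } else numeric(length(breaks) - 1L)
  data.frame(zt_h = breaks[-length(breaks)],
             events_per_min = moving_average(counts, window_min))
}

#' Phonotaxis index per playback interval
#'
#' For each playback interval (one tone presentation per 30-min interval
#' in the playback protocol), the proportion of all flyby events in the
#' interval that occur during the playback minute. Intervals with zero
#' events are flagged undefined (`NA`), not zero.
#'
#' @param events Event table (`start_s` used, seconds from recording
#'   start).
#' @param playback_intervals data.frame with `interval_start_s`,
#'   `interval_end_s`, `playback_start_s`, `playback_end_s`.
#' @return data.frame with the interval bounds plus `n_events`,
#'   `n_during_playback`, `index` (`NA` when undefined).
#' @export
phonotaxis_index <- function(events, playback_intervals) {
  stopifnot(all(c("interval_start_s", "interval_end_s", "playback_start_s",
                  "playback_end_s") %in% names(playback_intervals)))
  out <- playback_intervals
  out$n_events <- NA_integer_; out$n_during_playback <- NA_integer_
  out$index <- NA_real_
  for (i in seq_len(nrow(out))) {
    in_int <- events$start_s >= out$interval_start_s[i] &
      events$start_s < out$interval_end_s[i]
    in_pb <- in_int & events$start_s >= out$playback_start_s[i] &
      events$start_s < out$playback_end_s[i]
    out$n_events[i] <- sum(in_int)
    out$n_during_playback[i] <- sum(in_pb)
    out$index[i] <- if (sum(in_int) > 0) sum(in_pb) / sum(in_int)
      else NA_real_
  }
  out
}
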