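#' Synthesize a beam-break actogram with known circadian structure
#'
#' Emulates TriKinetics-style infrared beam-break counts binned at 1-min
#' intervals: each day carries one main activity bout (the dusk bout, onset
#' ZT13 by default) plus optional lights-on startle activity and a low
#' Poisson background. Entrained days place the bout at `bout_onset_zt`;
#' free-running days advance it by `(24 - period_h)` hours per day, the
#' drift signature of a clock running faster than 24 h (males free-run at
#' about 22.64 h).
#'
#' @param period_h Endogenous free-running period (h).
#' @param bout_onset_zt Bout onset on entrained days (ZT h).
#' @param bout_len_h Bout duration (h).
#' @param days Total days simulated.
#' @param entrained_days Leading days under light:dark entrainment; the
#'   remaining days free-run.
#' @param bin_min Bin width (min).
#' @param n_tubes Number of activity tubes (columns).
#' @param bout_rate Mean counts/bin/tube inside a bout.
#' @param noise_rate Mean background counts/bin/tube.
#' @param startle Add a 10-min lights-on startle bout at ZT0 on entrained
#'   days.
#' @param seed Optional integer seed.
#' @return An `activity_series` (see [activity_series()]) with attribute
#'   `ground_truth`: data.frame of per-day bout onsets (`day`,
#'   `onset_zt_h`, `duration_h`, `regime`).
#' @export
#' @examples
#' act <- synth_actogram(period_h = 22.64, days = 5, entrained_days = 0,
#'                       seed = 1)
#' head(attr(act, "ground_truth"))
synth_actogram <- function(period_h = 24, bout_onset_zt = 13,
                           bout_len_h = 0.5, days = 3, entrained_days = days,
                           bin_min = 1, n_tubes = 1, bout_rate = 5,
                           noise_rate = 0.05, startle = FALSE, seed = NULL) {
  if (!is.finite(period_h) || period_h <= 0)
    stop_invalid("period_h must be positive")
  if (days < 1) stop_invalid("days must be >= 1")
  entrained_days <- min(entrained_days, days)
  bins_per_day <- round(24 * 60 / bin_min)
  n_bins <- bins_per_day * days
  zt_h <- (seq_len(n_bins) - 1L) * bin_min / 60
  rate <- rep(noise_rate, n_bins)
  gt <- data.frame(day = integer(0), onset_zt_h = numeric(0),
                   duration_h = numeric(0), regime = character(0))
  for (d in seq_len(days)) {
    free_days <- max(0L, d - entrained_days)
    onset <- bout_onset_zt - free_days * (24 - period_h)
    regime <- if (d <= entrained_days) "entrained" else "free_run"
    abs_onset <- (d - 1L) * 24 + onset
    sel <- zt_h >= abs_onset & zt_h < abs_onset + bout_len_h
    rate[sel] <- rate[sel] + bout_rate
    if (startle && regime == "entrained") {
      s0 <- (d - 1L) * 24
      sel <- zt_h >= s0 & zt_h < s0 + 10 / 60
      rate[sel] <- rate[sel] + bout_rate
    }
    gt <- rbind(gt, data.frame(day = d, onset_zt_h = onset %% 24,
                               duration_h = bout_len_h, regime = regime))
  }
  counts <- with_seed(seed, {
    matrix(rpois(n_bins * n_tubes, rep(rate, n_tubes)),
           nrow = n_bins, ncol = n_tubes)
  })
  colnames(counts) <- sprintf("tube%02d", seq_len(n_tubes))
  out <- activity_series(counts, bin_min = bin_min,
                         regime = rep(c("entrained", "free_run"),
                                      c(entrained_days,
                                        days - entrained_days)))
  attr(out, "ground_truth") <- gt
  out
}

#' Construct an activity series
#'
#' Binned locomotor (or flyby) counts on a Zeitgeber-time axis.
#'
#' @param counts Integer matrix, bins x tubes (a vector is treated as one
#'   tube).
#' @param bin_min Bin width (min).
#' @param zt0_h ZT hour of the first bin.
#' @param regime Optional character vector, per-day regime labels.
#' @return An `activity_series`: list with `counts`, `bin_min`, `zt_h`
#'   (absolute hours from experiment start, day 1 ZT0 = 0), `regime`.
#' @export
activity_series <- function(counts, bin_min = 1, zt0_h = 0, regime = NULL) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1L)
  if (any(counts < 0, na.rm = TRUE))
    stop_invalid("activity counts must be non-negative")
  n_bins <- nrow(counts)
  structure(list(counts = counts, bin_min = bin_min,
                 zt_h = zt0_h + (seq_len(n_bins) - 1L) * bin_min / 60,
                 regime = regime),
            class = "activity_series")
}
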