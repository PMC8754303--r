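#' Simulate a flight-tone trace as a mean-reverting frequency walk
#'
#' Generates the instantaneous fundamental frequency of one flying mosquito
#' as a stationary Ornstein-Uhlenbeck process: the trace reverts to
#' `mean_hz` with relaxation time `reversion_time_s` and has stationary
#' standard deviation `sd_hz`, matching the per-cohort mean and sigma of
#' recorded flight tones while producing realistic second-scale excursions.
#' The exact discrete-time transition is used, so results are independent of
#' further time-step subdivision.
#'
#' @param mean_hz Stationary mean frequency (Hz).
#' @param sd_hz Stationary standard deviation (Hz); 0 gives a constant trace.
#' @param duration_s Trace duration (s).
#' @param rate_hz Sampling rate of the trace (Hz); 10 Hz is the working
#'   resolution of the harmonic-convergence analyses.
#' @param reversion_time_s Relaxation time of the mean reversion (s). The
#'   within-flight frequency autocorrelation of real recordings is not
#'   published; 5 s is a plausibility default, not a measured value.
#' @param seed Optional integer seed; same seed implies an identical trace.
#' @return A `flight_tone_trace`: data.frame with columns `time_s`, `freq_hz`
#'   and attributes `rate_hz`, `mean_hz`, `sd_hz`.
#' @export
#' @examples
#' tr <- make_flight_tone_trace(844, 55, duration_s = 60, seed = 1)
#' c(mean(tr$freq_hz), sd(tr$freq_hz))
make_flight_tone_trace <- function(mean_hz, sd_hz, duration_s,
                                   rate_hz = 10, reversion_time_s = 5,
                                   seed = NULL) {
  if (!is.finite(duration_s) || duration_s <= 0)
    stop_invalid("duration_s must be positive, got %s", format(duration_s))
  if (!is.finite(rate_hz) || rate_hz <= 0)
    stop_invalid("rate_hz must be positive, got %s", format(rate_hz))
  if (sd_hz < 0) stop_invalid("sd_hz must be >= 0")
  if (mean_hz <= 0) stop_invalid("mean_hz must be > 0")
  n <- max(1L, round(duration_s * rate_hz))
  dt <- 1 / rate_hz
  freq <- with_seed(seed, {
    if (sd_hz == 0) rep(mean_hz, n)
    else {
      rho <- exp(-dt / reversion_time_s)
      innov_sd <- sd_hz * sqrt(1 - rho^2)
      x <- numeric(n)
      x[1] <- rnorm(1, mean_hz, sd_hz)
      eps <- rnorm(n - 1L, 0, innov_sd)
      for (i in seq_len(n - 1L))
        x[i + 1L] <- mean_hz + rho * (x[i] - mean_hz) + eps[i]
      x
    }
  })
  flight_tone_trace(time_s = (seq_len(n) - 1L) * dt, freq_hz = freq,
                    rate_hz = rate_hz, mean_hz = mean_hz, sd_hz = sd_hz)
}

#' Generate a pool of lone-flight traces with phonotype structure
#'
#' Emulates a library of 1-min lone-flight recordings: each individual has
#' a narrowband phonotype (individual mean drawn around the population
#' mean, small within-flight SD), so pairs assembled from the pool vary in
#' how close their fundamental ratio accidentally lies to 3:2 — the
#' structure that makes harmonic-convergence counts a function of the
#' pair's distance from the ratio.
#'
#' @param n Number of individuals/traces.
#' @param mean_hz Population mean frequency (Hz).
#' @param between_sd_hz SD of individual means around the population mean.
#' @param within_sd_hz Within-flight SD of each trace.
#' @param duration_s Trace duration (s).
#' @param rate_hz Trace sampling rate (Hz).
#' @param reversion_time_s Mean-reversion time (s).
#' @param seed Optional integer seed.
#' @return List of `flight_tone_trace`.
#' @export
synth_trace_pool <- function(n, mean_hz, between_sd_hz = 30,
                             within_sd_hz = 20, duration_s = 60,
                             rate_hz = 10, reversion_time_s = 5,
                             seed = NULL) {
  with_seed(seed, {
    means <- rnorm(n, mean_hz, between_sd_hz)
    lapply(seq_len(n), function(i)
      make_flight_tone_trace(means[i], within_sd_hz, duration_s,
                             rate_hz = rate_hz,
                             reversion_time_s = reversion_time_s))
  })
}

#' Construct a flight-tone trace object
#'
#' @param time_s,freq_hz Equal-length numeric vectors (s, Hz).
#' @param rate_hz Sampling rate (Hz); inferred from `time_s` if missing.
#' @param mean_hz,sd_hz Optional generating parameters, kept as metadata.
#' @return A `flight_tone_trace` data.frame.
#' @export
flight_tone_trace <- function(time_s, freq_hz, rate_hz = NULL,
                              mean_hz = NA_real_, sd_hz = NA_real_) {
  if (length(time_s) != length(freq_hz))
    stop_invalid("time_s and freq_hz must have equal length")
  if (is.null(rate_hz)) {
    rate_hz <- if (length(time_s) > 1L) 1 / median(diff(time_s)) else NA_real_
  }
  structure(data.frame(time_s = time_s, freq_hz = freq_hz),
            rate_hz = rate_hz, mean_hz = mean_hz, sd_hz = sd_hz,
            class = c("flight_tone_trace", "data.frame"))
}

#' Generate a population of individual phonotypes
#'
#' Individual mosquitoes occupy narrow, partly non-overlapping frequency
#' bands ("phonotypes"): between-individual spread is wider than the
#' within-individual spread. Individual baseline means are drawn around the
#' sex/state population mean; male state means preserve the circadian
#' ordering baseline < swarming < activated, while female states differ
#' only negligibly.
#'
#' @param n_individuals Number of individuals.
#' @param sex `"male"` or `"female"`.
#' @param state_means_hz Named vector of population state means
#'   (`baseline`, `swarming`, `activated`); defaults to the measured male
#'   states 751/844/900 Hz or a flat ~550 Hz for females.
#' @param between_sd_hz SD of individual offsets from the population mean.
#' @param within_sd_hz Within-individual flight-tone SD.
#' @param seed Optional integer seed.
#' @return A `phonotype_population`: data.frame with one row per individual,
#'   columns `individual_id`, `sex`, `baseline_hz`, `swarming_hz`,
#'   `activated_hz`, `within_sd_hz`.
#' @export
phonotype_population <- function(n_individuals, sex = c("male", "female"),
                                 state_means_hz = NULL,
                                 between_sd_hz = 30, within_sd_hz = 20,
                                 seed = NULL) {
  sex <- match.arg(sex)
  if (n_individuals < 1) stop_invalid("n_individuals must be >= 1")
  if (is.null(state_means_hz)) {
    state_means_hz <- if (sex == "male") male_state_means()
      else c(baseline = 547, swarming = 556, activated = 556)
  }
  stopifnot(all(c("baseline", "swarming", "activated") %in%
                  names(state_means_hz)))
  offs <- with_seed(seed, rnorm(n_individuals, 0, between_sd_hz))
  pop <- data.frame(
    individual_id = sprintf("%s%02d", toupper(substr(sex, 1, 1)),
                            seq_len(n_individuals)),
    sex = sex,
    baseline_hz = state_means_hz[["baseline"]] + offs,
    swarming_hz = state_means_hz[["swarming"]] + offs,
    activated_hz = state_means_hz[["activated"]] + offs,
    within_sd_hz = within_sd_hz,
    stringsAsFactors = FALSE)
  if (sex == "male" && any(pop$swarming_hz < pop$baseline_hz))
    stop_invalid("male state means must preserve swarming >= baseline")
  class(pop) <- c("phonotype_population", "data.frame")
  pop
}
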