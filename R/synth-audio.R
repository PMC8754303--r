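#' Configuration for synthetic cage-audio recordings
#'
#' Describes one emulated single-sex cage recording: microphone sample rate
#' (recordings are made at 50 kHz per channel), flyby rates per behavioural
#' state, the harmonic amplitude profile of the synthesized wingbeat tone,
#' the narrow-band mechanical noise bursts the environmental chamber
#' injects (~30 ms at 653 +/- 3.7 Hz), and the Gaussian background floor.
#'
#' @param sample_rate Audio sample rate (Hz).
#' @param duration_s Recording duration (s).
#' @param flyby_rate_per_min Named numeric vector: mean flyby events/min in
#'   each behavioural state (names matching the `zt_schedule` states).
#' @param flyby_len_s Range (min, max) of flyby durations (s), drawn
#'   uniformly.
#' @param harmonic_amplitudes Relative amplitudes of harmonics 1..k of the
#'   synthesized tone. Only frequency ratios matter downstream; the default
#'   1/0.5/0.3/0.15 roll-off is a plumbing choice.
#' @param flyby_amplitude Peak amplitude of a flyby tone (arbitrary units).
#' @param noise_burst List with `center_hz`, `sd_hz`, `length_s`,
#'   `rate_per_min`, `amplitude` for chamber noise bursts.
#' @param background_rms RMS of the Gaussian background floor.
#' @param ramp_s Raised-cosine on/off ramp applied to every inserted event.
#' @param trace_rate_hz Sampling rate of the underlying frequency walk.
#' @param reversion_time_s Mean-reversion time of the frequency walk (s).
#' @param seed Optional integer seed.
#' @return A list of class `cage_sim_config`.
#' @export
cage_sim_config <- function(sample_rate = 50000, duration_s = 60,
                            flyby_rate_per_min = c(baseline = 0.5,
                                                   swarming = 6,
                                                   activated = 6),
                            flyby_len_s = c(0.3, 1.5),
                            harmonic_amplitudes = c(1, 0.5, 0.3, 0.15),
                            flyby_amplitude = 0.2,
                            noise_burst = list(center_hz = 653, sd_hz = 3.7,
                                               length_s = 0.03,
                                               rate_per_min = 0,
                                               amplitude = 0.2),
                            background_rms = 0.005,
                            ramp_s = 0.05, trace_rate_hz = 100,
                            reversion_time_s = 5, seed = NULL) {
  nb <- modifyList(list(center_hz = 653, sd_hz = 3.7, length_s = 0.03,
                        rate_per_min = 0, amplitude = 0.2), noise_burst)
  if (any(flyby_rate_per_min < 0) || nb$rate_per_min < 0)
    stop_invalid("event rates must be >= 0")
  max_harm <- length(harmonic_amplitudes)
  if (sample_rate <= 0 || duration_s <= 0)
    stop_invalid("sample_rate and duration_s must be positive")
  structure(list(sample_rate = sample_rate, duration_s = duration_s,
                 flyby_rate_per_min = flyby_rate_per_min,
                 flyby_len_s = flyby_len_s,
                 harmonic_amplitudes = harmonic_amplitudes,
                 flyby_amplitude = flyby_amplitude,
                 noise_burst = nb, background_rms = background_rms,
                 ramp_s = ramp_s, trace_rate_hz = trace_rate_hz,
                 reversion_time_s = reversion_time_s,
                 n_harmonics = max_harm, seed = seed),
            class = "cage_sim_config")
}

#' Default Zeitgeber-time schedule of behavioural states
#'
#' Swarm time is the hour centred on the circadian sunset at ZT13
#' (lights-off); all other times are baseline.
#'
#' @param swarm_center_zt Centre of the swarm window (ZT hours).
#' @param half_width_h Half-width of the swarm window (hours).
#' @return data.frame with columns `zt_from`, `zt_to`, `state`.
#' @export
default_zt_schedule <- function(swarm_center_zt = 13, half_width_h = 0.5) {
  lo <- swarm_center_zt - half_width_h
  hi <- swarm_center_zt + half_width_h
  data.frame(zt_from = c(0, lo, hi), zt_to = c(lo, hi, 24),
             state = c("baseline", "swarming", "baseline"),
             stringsAsFactors = FALSE)
}

state_at_zt <- function(zt, schedule) {
  zt <- zt %% 24
  hit <- which(schedule$zt_from <= zt & zt < schedule$zt_to)
  if (!length(hit)) "baseline" else schedule$state[hit[1L]]
}

raised_cosine_ramp <- function(n, n_ramp) {
  env <- rep(1, n)
  n_ramp <- min(n_ramp, n %/% 2L)
  if (n_ramp > 0L) {
    up <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp))
    env[seq_len(n_ramp)] <- up
    env[n - n_ramp + seq_len(n_ramp)] <- rev(up)
  }
  env
}

# Multi-harmonic tone whose fundamental follows `freq_trace` (sampled at
# trace_rate_hz), phase-continuous at the audio rate.
synth_harmonic_tone <- function(freq_trace, trace_rate_hz, n_samples,
                                sample_rate, harmonic_amplitudes, ramp_n) {
  tt <- (seq_along(freq_trace) - 1L) / trace_rate_hz
  ts <- (seq_len(n_samples) - 1L) / sample_rate
  f_inst <- approx(tt, freq_trace, xout = ts, rule = 2)$y
  phase <- 2 * pi * cumsum(f_inst) / sample_rate
  sig <- numeric(n_samples)
  for (h in seq_along(harmonic_amplitudes))
    sig <- sig + harmonic_amplitudes[h] * sin(h * phase)
  sig * raised_cosine_ramp(n_samples, ramp_n) / sum(harmonic_amplitudes)
}

# Poisson event starts over [0, duration_s] at a piecewise-constant rate set
# by the ZT schedule; overlapping events are dropped (keep-first).
draw_event_times <- function(duration_s, start_zt_h, rate_per_min_by_state,
                             schedule, len_range_s) {
  n_guess <- rpois(1, max(rate_per_min_by_state) / 60 * duration_s)
  cand <- sort(runif(n_guess, 0, duration_s))
  keep_p <- vapply(cand, function(s) {
    st <- state_at_zt(start_zt_h + s / 3600, schedule)
    r <- rate_per_min_by_state[[st]]
    r / max(rate_per_min_by_state)
  }, numeric(1))
  cand <- cand[runif(length(cand)) < keep_p]
  lens <- runif(length(cand), len_range_s[1], len_range_s[2])
  ends <- cand + lens
  keep <- rep(TRUE, length(cand))
  last_end <- -Inf
  for (i in seq_along(cand)) {
    if (cand[i] < last_end || ends[i] > duration_s) keep[i] <- FALSE
    else last_end <- ends[i]
  }
  data.frame(start_s = cand[keep], end_s = ends[keep])
}

#' Synthesize a cage audio recording with ground truth
#'
#' Emulates a single-microphone recording from a single-sex cage: flybys are
#' windowed multi-harmonic tones whose fundamental follows a mean-reverting
#' frequency walk for a randomly chosen individual in the behavioural state
#' given by the Zeitgeber-time schedule; short narrow-band chamber noise
#' bursts and a Gaussian background floor are added. Every inserted event is
#' listed in the returned ground-truth table, so detector recovery can be
#' scored exactly.
#'
#' @param population A `phonotype_population` (may have 0 rows only if all
#'   flyby rates are 0).
#' @param config A `cage_sim_config`.
#' @param zt_schedule data.frame mapping ZT intervals to states; see
#'   [default_zt_schedule()].
#' @param start_zt_h ZT hour at which the recording starts.
#' @return List of class `cage_audio`: `samples` (numeric), `sample_rate`,
#'   `start_zt_h`, `ground_truth` (data.frame: `start_s`, `end_s`,
#'   `freq_hz`, `kind`, `individual_id`, `state`).
#' @export
synth_cage_audio <- function(population, config = cage_sim_config(),
                             zt_schedule = default_zt_schedule(),
                             start_zt_h = 13) {
  any_flyby <- any(config$flyby_rate_per_min > 0)
  if (any_flyby && (is.null(population) || nrow(population) == 0L))
    stop_invalid("non-empty population required when flyby rate > 0")
  sr <- config$sample_rate
  max_f <- max(vapply(seq_len(nrow(population)),
                      function(i) max(population$baseline_hz[i],
                                      population$swarming_hz[i],
                                      population$activated_hz[i]),
                      numeric(1)), 0)
  if (any_flyby && sr < 2 * config$n_harmonics * max_f)
    stop_invalid("sample_rate below Nyquist for the highest harmonic")
  n <- round(config$duration_s * sr)
  ramp_n <- round(config$ramp_s * sr)
  with_seed(config$seed, {
    audio <- rnorm(n, 0, config$background_rms)
    gt <- list()
    if (any_flyby) {
      ev <- draw_event_times(config$duration_s, start_zt_h,
                             config$flyby_rate_per_min, zt_schedule,
                             config$flyby_len_s)
      for (i in seq_len(nrow(ev))) {
        st <- state_at_zt(start_zt_h + ev$start_s[i] / 3600, zt_schedule)
        ind <- population[sample.int(nrow(population), 1L), ]
        mu <- ind[[paste0(if (st == "swarming") "swarming"
                          else if (st == "activated") "activated"
                          else "baseline", "_hz")]]
        len_s <- ev$end_s[i] - ev$start_s[i]
        tr <- make_flight_tone_trace(mu, ind$within_sd_hz, len_s,
                                     rate_hz = config$trace_rate_hz,
                                     reversion_time_s = config$reversion_time_s)
        i0 <- round(ev$start_s[i] * sr) + 1L
        nseg <- min(round(len_s * sr), n - i0 + 1L)
        tone <- synth_harmonic_tone(tr$freq_hz, config$trace_rate_hz, nseg,
                                    sr, config$harmonic_amplitudes, ramp_n)
        audio[i0:(i0 + nseg - 1L)] <- audio[i0:(i0 + nseg - 1L)] +
          config$flyby_amplitude * tone
        gt[[length(gt) + 1L]] <- data.frame(
          start_s = ev$start_s[i], end_s = ev$end_s[i],
          freq_hz = mean(tr$freq_hz), kind = "flyby",
          individual_id = ind$individual_id, state = st,
          stringsAsFactors = FALSE)
      }
    }
    nb <- config$noise_burst
    if (nb$rate_per_min > 0) {
      n_b <- rpois(1, nb$rate_per_min / 60 * config$duration_s)
      starts <- sort(runif(n_b, 0, config$duration_s - nb$length_s))
      for (s0 in starts) {
        f <- rnorm(1, nb$center_hz, nb$sd_hz)
        i0 <- round(s0 * sr) + 1L
        nseg <- round(nb$length_s * sr)
        if (i0 + nseg - 1L > n) next
        tt <- (seq_len(nseg) - 1L) / sr
        burst <- nb$amplitude * sin(2 * pi * f * tt) *
          raised_cosine_ramp(nseg, min(ramp_n, nseg %/% 4L))
        audio[i0:(i0 + nseg - 1L)] <- audio[i0:(i0 + nseg - 1L)] + burst
        gt[[length(gt) + 1L]] <- data.frame(
          start_s = s0, end_s = s0 + nb$length_s, freq_hz = f,
          kind = "noise", individual_id = NA_character_,
          state = NA_character_, stringsAsFactors = FALSE)
      }
    }
    gt <- if (length(gt)) {
      gt <- do.call(rbind, gt)
      gt[order(gt$start_s), , drop = FALSE]
    } else {
      data.frame(start_s = numeric(0), end_s = numeric(0),
                 freq_hz = numeric(0), kind = character(0),
                 individual_id = character(0), state = character(0),
                 stringsAsFactors = FALSE)
    }
    structure(list(samples = audio, sample_rate = sr,
                   start_zt_h = start_zt_h, ground_truth = gt),
              class = "cage_audio")
  })
}
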