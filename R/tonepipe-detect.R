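#' Detect flyby events by relative envelope threshold
#'
#' A moving-average envelope is computed across the fully rectified signal;
#' samples where the envelope exceeds twice the rectified local mean are
#' event candidates. Maximal runs separated by less than `gap_merge_ms` are
#' merged (envelope dropouts within one flyby), then runs shorter than
#' `min_len_ms` are discarded. Raising the minimum event length above the
#' ~30-ms duration of chamber noise bursts is the noise-rejection rule:
#' it is tuned until a light-phase recording (when mosquitoes do not fly)
#' yields zero events.
#'
#' Because the threshold is relative (2x the local mean), detection is
#' invariant to overall amplitude scaling of the input.
#'
#' @param segment A preprocessed `audio_segment`.
#' @param env_window_ms Envelope moving-average window (ms).
#' @param min_len_ms Minimum event length (ms); typically set just above
#'   30 ms.
#' @param local_span_s Span of the rectified local-mean window (s). `Inf`
#'   (or `NULL`) uses the whole-segment mean, appropriate when events can
#'   occupy a large fraction of the segment (e.g. long playback tones).
#' @param gap_merge_ms Events separated by less than this are merged (ms).
#' @param threshold_factor Envelope-to-local-mean ratio required (default
#'   2).
#' @return data.frame with columns `start_s`, `end_s`, sorted and
#'   non-overlapping.
#' @export
detect_flybys <- function(segment, env_window_ms = 50, min_len_ms = 100,
                          local_span_s = 5, gap_merge_ms = 50,
                          threshold_factor = 2) {
  stopifnot(inherits(segment, "audio_segment"))
  if (env_window_ms <= 0) stop_invalid("env_window_ms must be positive")
  sr <- segment$sample_rate
  n <- length(segment$samples)
  env_n <- round(env_window_ms / 1000 * sr)
  if (env_n > n)
    stop_invalid("envelope window (%g ms) longer than segment", env_window_ms)
  rect <- abs(segment$samples)
  env <- moving_average(rect, env_n)
  if (is.null(local_span_s) || !is.finite(local_span_s)) {
    local <- rep(mean(rect), n)
  } else {
    local <- moving_average(rect, round(local_span_s * sr))
  }
  flag <- env > threshold_factor * local
  runs <- true_runs(flag)
  if (!nrow(runs))
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  start_s <- (runs$start - 1L) / sr
  end_s <- runs$end / sr
  # the centered moving-average envelope widens a burst by half the
  # window on each side; contract the bounds so event durations are
  # measured at the signal, not the envelope, scale
  half_w <- env_n / 2 / sr
  start_s <- start_s + half_w
  end_s <- end_s - half_w
  ok <- end_s > start_s
  start_s <- start_s[ok]; end_s <- end_s[ok]
  if (!length(start_s))
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  # merge gaps shorter than gap_merge_ms
  gap <- gap_merge_ms / 1000
  keep_start <- start_s[1]
  out_s <- numeric(0); out_e <- numeric(0)
  cur_e <- end_s[1]
  for (i in seq_along(start_s)[-1]) {
    if (start_s[i] - cur_e < gap) {
      cur_e <- end_s[i]
    } else {
      out_s <- c(out_s, keep_start); out_e <- c(out_e, cur_e)
      keep_start <- start_s[i]; cur_e <- end_s[i]
    }
  }
  out_s <- c(out_s, keep_start); out_e <- c(out_e, cur_e)
  len_ok <- (out_e - out_s) >= min_len_ms / 1000
  data.frame(start_s = out_s[len_ok], end_s = out_e[len_ok])
}
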