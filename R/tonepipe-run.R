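#' Pipeline stage parameters
#'
#' @param low_hz,high_hz Band-pass corners (Hz); `playback_mode = TRUE`
#'   switches the low corner to 600 Hz so the 550-Hz artificial female
#'   tone is excluded from detection.
#' @param playback_mode Use playback corner frequencies (600/1200 Hz).
#' @param env_window_ms,min_len_ms,local_span_s,gap_merge_ms Detection
#'   parameters, see [detect_flybys()].
#' @param window_ms,slide_frac,r2_min,grid_hz Fit parameters, see
#'   [extract_flight_tone()].
#' @param chunk_s Recording chunk length for processing (s).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(low_hz = 300, high_hz = 1200,
                            playback_mode = FALSE,
                            env_window_ms = 50, min_len_ms = 100,
                            local_span_s = 5, gap_merge_ms = 50,
                            window_ms = 10, slide_frac = 0.5, r2_min = 0.9,
                            grid_hz = 1, chunk_s = 60) {
  if (playback_mode) low_hz <- max(low_hz, 600)
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 env_window_ms = env_window_ms, min_len_ms = min_len_ms,
                 local_span_s = local_span_s, gap_merge_ms = gap_merge_ms,
                 window_ms = window_ms, slide_frac = slide_frac,
                 r2_min = r2_min, grid_hz = grid_hz, chunk_s = chunk_s),
            class = "pipeline_config")
}

empty_event_table <- function() {
  data.frame(channel = character(0), zt_h = numeric(0),
             start_s = numeric(0), end_s = numeric(0),
             median_freq_hz = numeric(0), n_valid_fits = integer(0),
             stringsAsFactors = FALSE)
}

#' Run the full flight-tone extraction pipeline on one recording
#'
#' Segments the recording into chunks (1 min by default), band-pass
#' filters each chunk, detects flyby events by relative envelope
#' threshold, stitches events touching chunk boundaries (avoiding double
#' counting), and extracts each event's flight tone as the median of
#' sliding sinusoid fits with `r2 > r2_min`. Events whose fits never pass
#' the `r2` criterion are dropped.
#'
#' @param recording An `audio_segment`, a `cage_audio` from
#'   [synth_cage_audio()], or a path to a WAV file (channels are processed
#'   independently).
#' @param config A [pipeline_config()].
#' @return data.frame of events: `channel`, `zt_h` (ZT hour of event
#'   start), `start_s`, `end_s` (s from recording start),
#'   `median_freq_hz`, `n_valid_fits`.
#' @export
run_pipeline <- function(recording, config = pipeline_config()) {
  if (is.character(recording)) {
    wav <- read_wav(recording)
    segs <- lapply(seq_len(ncol(wav$samples)), function(ch)
      audio_segment(wav$samples[, ch], wav$sample_rate,
                    channel_id = sprintf("ch%d", ch)))
    out <- lapply(segs, run_pipeline, config = config)
    return(do.call(rbind, out))
  }
  if (inherits(recording, "cage_audio")) {
    recording <- audio_segment(recording$samples, recording$sample_rate,
                               start_zt_h = recording$start_zt_h)
  }
  stopifnot(inherits(recording, "audio_segment"))
  sr <- recording$sample_rate
  n <- length(recording$samples)
  chunk_n <- round(config$chunk_s * sr)
  chunk_starts <- seq(1L, n, by = chunk_n)
  events <- list(); filtered <- list()
  for (ci in seq_along(chunk_starts)) {
    i0 <- chunk_starts[ci]
    i1 <- min(n, i0 + chunk_n - 1L)
    if (i1 - i0 + 1L < round(config$env_window_ms / 1000 * sr)) next
    seg <- audio_segment(recording$samples[i0:i1], sr,
                         channel_id = recording$channel_id)
    seg <- preprocess(seg, config$low_hz, config$high_hz)
    filtered[[ci]] <- seg$samples
    ev <- detect_flybys(seg, config$env_window_ms, config$min_len_ms,
                        config$local_span_s, config$gap_merge_ms)
    if (nrow(ev)) {
      ev$start_s <- ev$start_s + (i0 - 1L) / sr
      ev$end_s <- ev$end_s + (i0 - 1L) / sr
      events[[length(events) + 1L]] <- ev
    }
  }
  if (!length(events)) return(empty_event_table())
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$start_s), , drop = FALSE]
  # stitch events split by a chunk boundary
  stitch_gap <- config$gap_merge_ms / 1000
  i <- 1L
  while (i < nrow(ev)) {
    if (ev$start_s[i + 1L] - ev$end_s[i] < stitch_gap) {
      ev$end_s[i] <- ev$end_s[i + 1L]
      ev <- ev[-(i + 1L), , drop = FALSE]
    } else i <- i + 1L
  }
  full_filtered <- numeric(n)
  for (ci in seq_along(chunk_starts)) {
    if (is.null(filtered[[ci]])) next
    i0 <- chunk_starts[ci]
    full_filtered[i0:(i0 + length(filtered[[ci]]) - 1L)] <- filtered[[ci]]
  }
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    j0 <- max(1L, round(ev$start_s[i] * sr) + 1L)
    j1 <- min(n, round(ev$end_s[i] * sr))
    ft <- extract_flight_tone(full_filtered[j0:j1], sr,
                              band = c(config$low_hz, config$high_hz),
                              window_ms = config$window_ms,
                              slide_frac = config$slide_frac,
                              r2_min = config$r2_min,
                              grid_hz = config$grid_hz)
    if (is.null(ft)) return(NULL)
    data.frame(channel = recording$channel_id,
               zt_h = (recording$start_zt_h + ev$start_s[i] / 3600) %% 24,
               start_s = ev$start_s[i], end_s = ev$end_s[i],
               median_freq_hz = ft$median_freq_hz,
               n_valid_fits = ft$n_valid_fits,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_event_table())
  do.call(rbind, rows)
}
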