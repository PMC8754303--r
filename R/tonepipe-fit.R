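#' Fit a general sinusoid to one short window
#'
#' Finds the frequency `x` maximizing the variance explained by the model
#' `a*sin(2*pi*x*t) + b*cos(2*pi*x*t)`, with `a`, `b` solved by linear
#' least squares at each candidate frequency. The search localizes the
#' spectral peak with a zero-padded periodogram, refines it on a `grid_hz`
#' grid around the peak, and finishes with parabolic interpolation of the
#' residual curve. `r2 = 1 - SS_resid / SS_total`; windows with `r2` below
#' the downstream threshold (0.9) are excluded from event medians.
#'
#' @param window Numeric samples of one fit window (10 ms at the audio
#'   rate in the standard pipeline).
#' @param sample_rate Sample rate (Hz).
#' @param band Numeric `(low_hz, high_hz)` search band; should lie within
#'   the preprocessing corners.
#' @param grid_hz Grid resolution of the fine frequency search (Hz).
#' @return A list (class `fit_window_result`): `freq_hz`, `r2`,
#'   `amplitude`, `phase`, `valid` (FALSE for degenerate all-zero
#'   windows).
#' @export
fit_sinusoid_window <- function(window, sample_rate,
                                band = c(300, 1200), grid_hz = 1) {
  n <- length(window)
  ss_tot <- sum((window - mean(window))^2)
  if (ss_tot <= 0 || all(window == 0)) {
    return(structure(list(freq_hz = NA_real_, r2 = 0, amplitude = 0,
                          phase = NA_real_, valid = FALSE),
                     class = "fit_window_result"))
  }
  t <- (seq_len(n) - 1L) / sample_rate
  # coarse localization: zero-padded periodogram restricted to the band
  nfft <- 2^ceiling(log2(max(16L * n, 1024L)))
  spec <- Mod(fft(c(window - mean(window), numeric(nfft - n))))[
    seq_len(nfft %/% 2L)]
  fax <- (seq_len(nfft %/% 2L) - 1L) * sample_rate / nfft
  in_band <- fax >= band[1] & fax <= band[2]
  if (!any(in_band)) stop_invalid("search band contains no frequency bin")
  f0 <- fax[in_band][which.max(spec[in_band])]
  # fine grid +/- 3 periodogram bins around the coarse peak
  half_span <- max(3 * sample_rate / nfft, 2 * grid_hz)
  cand <- seq(max(band[1], f0 - half_span), min(band[2], f0 + half_span),
              by = grid_hz)
  fit_at <- function(freqs) {
    ang <- outer(t, 2 * pi * freqs)
    S <- sin(ang); C <- cos(ang)
    y <- window
    Sy <- colSums(S * y); Cy <- colSums(C * y)
    Sss <- colSums(S * S); Scc <- colSums(C * C); Ssc <- colSums(S * C)
    det <- Sss * Scc - Ssc^2
    a <- (Sy * Scc - Cy * Ssc) / det
    b <- (Cy * Sss - Sy * Ssc) / det
    ss_res <- sum(y^2) - (a * Sy + b * Cy)
    list(a = a, b = b, ss_res = ss_res)
  }
  ft <- fit_at(cand)
  i_best <- which.min(ft$ss_res)
  f_best <- cand[i_best]
  # parabolic refinement on the residual curve
  if (i_best > 1L && i_best < length(cand)) {
    y1 <- ft$ss_res[i_best - 1L]; y2 <- ft$ss_res[i_best]
    y3 <- ft$ss_res[i_best + 1L]
    denom <- y1 - 2 * y2 + y3
    if (is.finite(denom) && denom > 0) {
      f_best <- f_best + grid_hz * 0.5 * (y1 - y3) / denom
    }
  }
  fr <- fit_at(f_best)
  r2 <- 1 - fr$ss_res / ss_tot
  structure(list(freq_hz = f_best, r2 = max(0, min(1, r2)),
                 amplitude = sqrt(fr$a^2 + fr$b^2),
                 phase = atan2(fr$b, fr$a), valid = TRUE),
            class = "fit_window_result")
}

#' Extract the flight tone of one detected event
#'
#' Slides a fit window (default 10 ms, 50% slide) across the event and fits
#' the general sinusoid in each window; the event's flight tone is the
#' median of all fitted frequencies whose fit had `r2 > r2_min` (default
#' 0.9). If no window passes, the event is dropped (returns `NULL`): noise
#' does not produce a flight tone, by contract.
#'
#' @param event_samples Numeric samples of the detected event
#'   (preprocessed).
#' @param sample_rate Sample rate (Hz).
#' @param band Frequency search band (Hz).
#' @param window_ms Fit window length (ms).
#' @param slide_frac Fractional slide between consecutive windows.
#' @param r2_min Minimum `r2` for a window fit to count.
#' @param grid_hz Frequency grid resolution (Hz).
#' @return List with `median_freq_hz`, `n_valid_fits`, `n_windows`, and the
#'   per-window `fits` data.frame (`window_start_s`, `freq_hz`, `r2`), or
#'   `NULL` if no window passed.
#' @export
extract_flight_tone <- function(event_samples, sample_rate,
                                band = c(300, 1200), window_ms = 10,
                                slide_frac = 0.5, r2_min = 0.9,
                                grid_hz = 1) {
  wn <- round(window_ms / 1000 * sample_rate)
  if (wn < 4L) stop_invalid("fit window too short (%d samples)", wn)
  hop <- max(1L, round(wn * slide_frac))
  starts <- seq(1L, max(1L, length(event_samples) - wn + 1L), by = hop)
  freq <- numeric(length(starts)); r2 <- numeric(length(starts))
  for (i in seq_along(starts)) {
    w <- event_samples[starts[i]:min(length(event_samples),
                                     starts[i] + wn - 1L)]
    f <- fit_sinusoid_window(w, sample_rate, band, grid_hz)
    freq[i] <- if (f$valid) f$freq_hz else NA_real_
    r2[i] <- f$r2
  }
  ok <- !is.na(freq) & r2 > r2_min
  if (!any(ok)) return(NULL)
  list(median_freq_hz = median(freq[ok]),
       n_valid_fits = sum(ok), n_windows = length(starts),
       fits = data.frame(window_start_s = (starts - 1L) / sample_rate,
                         freq_hz = freq, r2 = r2))
}
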