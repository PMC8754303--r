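#' Construct an audio segment
#'
#' @param samples Numeric vector of amplitudes (arbitrary units).
#' @param sample_rate Sample rate (Hz).
#' @param channel_id Channel label.
#' @param start_zt_h ZT hour of the first sample.
#' @return An `audio_segment` list.
#' @export
audio_segment <- function(samples, sample_rate, channel_id = "ch1",
                          start_zt_h = 0) {
  if (sample_rate <= 0) stop_invalid("sample_rate must be positive")
  if (any(!is.finite(samples)))
    stop_invalid("audio samples must be finite")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 channel_id = channel_id, start_zt_h = start_zt_h),
            class = "audio_segment")
}

# Polynomial coefficients (descending powers) from roots, real part kept.
poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  Re(p)
}

#' Design a digital Butterworth band-pass filter
#'
#' Butterworth band-pass from an order-`order` analog low-pass prototype
#' (MATLAB `butter(order, ...)` convention, i.e. `2 * order` poles in the
#' band-pass), via band transformation and bilinear transform with
#' frequency pre-warping. To keep the narrowband design numerically stable
#' the filter is returned as a cascade of fourth-order sections, one per
#' prototype conjugate pole pair, each normalized to unit gain at the
#' geometric centre frequency.
#'
#' @param low_hz,high_hz Corner (-3 dB) frequencies (Hz).
#' @param sample_rate Sample rate (Hz).
#' @param order Prototype order (default 4); must be even.
#' @return An `iir_cascade`: list of sections, each with numerator `b` and
#'   denominator `a`.
#' @export
butter_bandpass <- function(low_hz, high_hz, sample_rate, order = 4) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < sample_rate / 2))
    stop_invalid("corners must satisfy 0 < low < high < Nyquist (%g Hz)",
                 sample_rate / 2)
  if (order %% 2 != 0) stop_invalid("prototype order must be even")
  fs2 <- 2 * sample_rate
  wl <- fs2 * tan(pi * low_hz / sample_rate)
  wh <- fs2 * tan(pi * high_hz / sample_rate)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl
  f_center <- sqrt(low_hz * high_hz)
  sections <- lapply(seq_len(order / 2), function(k) {
    p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
    band_poles <- function(pp) {
      disc <- sqrt((pp * bw)^2 - 4 * w0^2 + 0i)
      c((pp * bw + disc) / 2, (pp * bw - disc) / 2)
    }
    sp <- c(band_poles(p), band_poles(Conj(p)))
    zp <- (fs2 + sp) / (fs2 - sp)
    if (any(Mod(zp) >= 1))
      stop_invalid("unstable filter section; widen the band or lower order")
    zz <- c(1, 1, -1, -1)
    sec <- list(b = poly_from_roots(zz), a = poly_from_roots(zp))
    g <- filter_response(structure(list(sections = list(sec)),
                                   class = "iir_cascade"),
                         f_center, sample_rate)
    sec$b <- sec$b / g
    sec
  })
  structure(list(sections = sections, low_hz = low_hz, high_hz = high_hz,
                 sample_rate = sample_rate, order = order),
            class = "iir_cascade")
}

#' Apply an IIR filter cascade
#'
#' Single forward pass through each section (use `zero_phase = TRUE` for
#' forward-backward filtering, which squares the magnitude response and
#' cancels phase delay).
#'
#' @param x Numeric signal.
#' @param filt An `iir_cascade` from [butter_bandpass()].
#' @param zero_phase Filter forward then backward.
#' @return Filtered signal, same length as `x`.
#' @export
iir_filter <- function(x, filt, zero_phase = FALSE) {
  one_pass <- function(x) {
    for (sec in filt$sections) {
      b <- sec$b / sec$a[1]
      a <- sec$a / sec$a[1]
      nb <- length(b)
      v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                         sides = 1)
      x <- as.numeric(stats::filter(as.numeric(v)[(nb - 1) + seq_along(x)],
                                    -a[-1], method = "recursive"))
    }
    x
  }
  if (!zero_phase) return(one_pass(x))
  # reflective padding damps edge transients of the backward pass
  n <- length(x)
  np <- min(n - 1L, 3L * 2L * length(filt$sections) * 4L * 25L)
  xp <- c(2 * x[1] - x[np:1 + 1L], x, 2 * x[n] - x[n - (1:np)])
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[np + seq_len(n)]
}

#' Magnitude response of a digital filter cascade
#'
#' @param filt An `iir_cascade`.
#' @param freq_hz Frequencies at which to evaluate (Hz).
#' @param sample_rate Sample rate (Hz).
#' @param zero_phase If `TRUE`, report the squared (forward-backward)
#'   response.
#' @return Magnitude (linear) at each frequency.
#' @export
filter_response <- function(filt, freq_hz, sample_rate, zero_phase = FALSE) {
  w <- 2 * pi * freq_hz / sample_rate
  evalp <- function(p, w)
    vapply(w, function(wi) sum(p * exp(-1i * wi * (seq_along(p) - 1))),
           complex(1))
  h <- rep(1 + 0i, length(w))
  for (sec in filt$sections)
    h <- h * evalp(sec$b, w) / evalp(sec$a, w)
  m <- Mod(h)
  if (zero_phase) m^2 else m
}

#' Band-pass preprocess a raw audio segment
#'
#' Removes any DC bias, then applies a Butterworth band-pass (order-4
#' prototype, zero-phase forward-backward pass). Default corners are 300
#' and 1200 Hz, bracketing mosquito fundamental flight tones; playback
#' experiments use 600/1200 Hz so the 550-Hz artificial female tone is
#' filtered out of the detection signal.
#'
#' @param segment An `audio_segment`.
#' @param low_hz,high_hz Corner frequencies (Hz).
#' @return The filtered `audio_segment`, with attribute `band`.
#' @export
preprocess <- function(segment, low_hz = 300, high_hz = 1200) {
  stopifnot(inherits(segment, "audio_segment"))
  filt <- butter_bandpass(low_hz, high_hz, segment$sample_rate)
  x <- segment$samples - mean(segment$samples)
  out <- segment
  out$samples <- iir_filter(x, filt, zero_phase = TRUE)
  attr(out, "band") <- c(low_hz, high_hz)
  out
}
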