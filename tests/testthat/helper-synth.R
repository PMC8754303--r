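# Shared fixtures and independent oracles, built in code at test time.

# Independent spectral oracle: argmax of a zero-padded periodogram.
fft_peak_hz <- function(x, sample_rate, band = c(100, 2000)) {
  n <- length(x)
  nfft <- 2^ceiling(log2(max(16 * n, 4096)))
  spec <- Mod(stats::fft(c(x - mean(x), numeric(nfft - n))))[
    seq_len(nfft %/% 2)]
  fax <- (seq_len(nfft %/% 2) - 1) * sample_rate / nfft
  keep <- fax >= band[1] & fax <= band[2]
  fax[keep][which.max(spec[keep])]
}

# A windowed tone with raised-cosine ramps, built independently of the
# package's synthesis path.
test_tone <- function(freq_hz, dur_s, sample_rate, amp = 0.2,
                      ramp_s = 0.05) {
  n <- round(dur_s * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  env <- rep(1, n)
  nr <- min(round(ramp_s * sample_rate), n %/% 2)
  if (nr > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- up
    env[n - nr + seq_len(nr)] <- rev(up)
  }
  amp * env * sin(2 * pi * freq_hz * tt)
}

# Insert a tone into background noise at a known offset.
embed_tone <- function(total_s, tone_start_s, tone, sample_rate,
                       noise_sd = 0.002, seed = 1) {
  set.seed(seed)
  x <- rnorm(round(total_s * sample_rate), 0, noise_sd)
  i0 <- round(tone_start_s * sample_rate) + 1
  x[i0:(i0 + length(tone) - 1)] <- x[i0:(i0 + length(tone) - 1)] + tone
  x
}

# Brute-force harmonic-convergence counter: explicit per-sample run scan,
# independent of the rle-based detector.
bf_hc_count <- function(pair, config = hc_config()) {
  m <- config$harmonic_pair[1]; nh <- config$harmonic_pair[2]
  rate <- pair$rate_hz
  dev <- abs(m * pair$male$freq_hz - nh * pair$female$freq_hz)
  inside <- !is.na(dev) & dev <= config$tol_hz
  count <- 0L; run <- 0L
  for (i in seq_along(inside)) {
    if (inside[i]) run <- run + 1L
    if (!inside[i] || i == length(inside)) {
      dur <- run / rate
      if (run > 0 && dur >= config$min_dur_s && dur <= config$max_dur_s)
        count <- count + 1L
      run <- 0L
    }
  }
  count
}

# Phonotype-structured lone pools for convergence statistics.
hc_pools <- function(n_males = 20, n_females = 20, seed = 1,
                     duration_s = 60) {
  list(males = synth_trace_pool(n_males, 900, between_sd_hz = 30,
                                within_sd_hz = 20,
                                duration_s = duration_s, seed = seed),
       females = synth_trace_pool(n_females, 600, between_sd_hz = 20,
                                  within_sd_hz = 15,
                                  duration_s = duration_s,
                                  seed = seed + 5000))
}
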