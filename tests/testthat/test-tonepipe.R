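sr <- 50000

test_that("band-pass preprocess removes DC and shapes the band", {
  # constant input -> zero output
  seg <- audio_segment(rep(0.7, sr), sr)
  out <- preprocess(seg)
  expect_lt(max(abs(out$samples)), 1e-4)

  # 550 Hz passband tone preserved within 1 dB (RMS oracle on the signal)
  tt <- (0:(2 * sr - 1)) / sr
  tone <- sin(2 * pi * 550 * tt)
  y <- preprocess(audio_segment(tone, sr))$samples
  amp <- sd(y[(sr %/% 2):(3 * sr %/% 2)]) * sqrt(2)
  expect_lt(abs(20 * log10(amp)), 1)

  # 100 Hz stopband tone attenuated by >= 40 dB
  tone_lo <- sin(2 * pi * 100 * tt)
  y_lo <- preprocess(audio_segment(tone_lo, sr))$samples
  amp_lo <- sd(y_lo[(sr %/% 2):(3 * sr %/% 2)]) * sqrt(2)
  expect_lt(20 * log10(amp_lo), -40)

  expect_error(preprocess(audio_segment(tone, sr), 300, 30000), "Nyquist")
})

test_that("sliding sinusoid fit recovers frequency on tones and rejects noise", {
  n <- round(0.010 * sr)
  tt <- (seq_len(n) - 1) / sr
  # clean tone: within the grid, near-perfect r2
  w <- sin(2 * pi * 550 * tt + 0.7)
  f <- fit_sinusoid_window(w, sr)
  expect_lt(abs(f$freq_hz - 550), 1)
  expect_gt(f$r2, 0.99)

  # SNR 10 dB: within 5 Hz of the independent periodogram oracle
  set.seed(4)
  wn <- w + rnorm(n, 0, sqrt(0.5 / 10^(10 / 10)))
  fn <- fit_sinusoid_window(wn, sr)
  expect_lt(abs(fn$freq_hz - 550), 5)
  expect_lt(abs(fn$freq_hz - fft_peak_hz(wn, sr, c(300, 1200))), 5)

  # pure noise rarely reaches the r2 > 0.9 acceptance criterion
  set.seed(5)
  r2s <- replicate(100, fit_sinusoid_window(rnorm(n), sr)$r2)
  expect_gt(mean(r2s < 0.9), 0.95)

  # degenerate all-zero window flagged invalid
  z <- fit_sinusoid_window(numeric(n), sr)
  expect_false(z$valid)
  expect_equal(z$r2, 0)
})

test_that("frequency estimator is unbiased across the band", {
  set.seed(6)
  freqs <- runif(50, 310, 1190)
  n <- round(0.010 * sr)
  tt <- (seq_len(n) - 1) / sr
  errs <- vapply(freqs, function(f0) {
    fit <- fit_sinusoid_window(sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi)),
                               sr)
    abs(fit$freq_hz - f0)
  }, numeric(1))
  expect_lt(max(errs), 1)  # grid resolution
})

test_that("flight-tone extraction medianizes r2-passing windows", {
  # constant 550 Hz event (the artificial female playback tone)
  tone <- test_tone(550, 1, sr, ramp_s = 0)
  ft <- extract_flight_tone(tone, sr)
  expect_lt(abs(ft$median_freq_hz - 550), 1)
  expect_gt(ft$n_valid_fits, 100)

  # modulated event: median fit tracks the ground-truth trace median
  tr <- make_flight_tone_trace(844, 20, 2, rate_hz = 100,
                               reversion_time_s = 1, seed = 8)
  ph <- 2 * pi * cumsum(approx(tr$time_s, tr$freq_hz,
                               xout = (0:(2 * sr - 1)) / sr,
                               rule = 2)$y) / sr
  ft2 <- extract_flight_tone(sin(ph), sr)
  expect_lt(abs(ft2$median_freq_hz - median(tr$freq_hz)), 5)

  # pure-noise event yields no flight tone
  set.seed(9)
  expect_null(extract_flight_tone(rnorm(sr %/% 2, 0, 1), sr))
})

test_that("envelope detector finds flybys and rejects noise bursts", {
  # background only
  set.seed(10)
  bg <- audio_segment(rnorm(5 * sr, 0, 0.002), sr)
  expect_equal(nrow(detect_flybys(bg)), 0)

  # one 500-ms flyby; bounds within 25 ms of the half-amplitude points of
  # its 50-ms raised-cosine ramps (2.025 / 2.475 s)
  x <- embed_tone(5, 2, test_tone(700, 0.5, sr), sr, seed = 11)
  ev <- detect_flybys(audio_segment(x, sr))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$start_s - 2.025), 0.025)
  expect_lt(abs(ev$end_s - 2.475), 0.025)

  # 30-ms noise bursts die at min_len 35 ms (the noise-rejection rule)
  set.seed(12)
  xb <- rnorm(5 * sr, 0, 0.002)
  burst <- test_tone(653, 0.03, sr, ramp_s = 0.005)
  for (s0 in c(1, 2.5, 4)) {
    i0 <- round(s0 * sr) + 1
    xb[i0:(i0 + length(burst) - 1)] <- xb[i0:(i0 + length(burst) - 1)] +
      burst
  }
  segb <- audio_segment(xb, sr)
  expect_equal(nrow(detect_flybys(segb, min_len_ms = 35)), 0)
  expect_gt(nrow(detect_flybys(segb, min_len_ms = 20)), 0)

  expect_error(detect_flybys(bg, env_window_ms = 10000), "window")
})

test_that("detection is monotone in min length and scale-invariant", {
  x <- embed_tone(6, 1, test_tone(700, 0.5, sr), sr, seed = 13)
  short_tone <- test_tone(653, 0.08, sr, ramp_s = 0.005)
  i0 <- round(3.5 * sr) + 1
  x[i0:(i0 + length(short_tone) - 1)] <-
    x[i0:(i0 + length(short_tone) - 1)] + short_tone
  seg <- audio_segment(x, sr)
  lens <- c(20, 50, 100, 300, 600)
  counts <- vapply(lens, function(L)
    nrow(detect_flybys(seg, min_len_ms = L)), integer(1))
  expect_true(all(diff(counts) <= 0))

  ev1 <- detect_flybys(seg)
  ev2 <- detect_flybys(audio_segment(7.3 * x, sr))
  expect_equal(ev1, ev2)
})

test_that("full pipeline recovers ground-truth flybys", {
  pop <- phonotype_population(4, "male", within_sd_hz = 10, seed = 20)
  cfg <- cage_sim_config(duration_s = 30,
                         flyby_rate_per_min = c(baseline = 0, swarming = 12,
                                                activated = 0),
                         seed = 21)
  cage <- synth_cage_audio(pop, cfg, start_zt_h = 13)
  gt <- cage$ground_truth
  gt <- gt[gt$end_s - gt$start_s >= 0.2, ]
  ev <- run_pipeline(cage)
  # at least 90% of sufficiently long ground-truth events recovered
  hits <- vapply(seq_len(nrow(gt)), function(i) {
    j <- which(ev$start_s < gt$end_s[i] & ev$end_s > gt$start_s[i])
    length(j) > 0 && abs(ev$median_freq_hz[j[1]] - gt$freq_hz[i]) < 10
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # silent recording -> empty table
  set.seed(22)
  silent <- audio_segment(rnorm(3 * sr, 0, 0.002), sr)
  expect_equal(nrow(run_pipeline(silent)), 0)
})
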