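test_that("frequency walk has the stated stationary moments", {
  # zero-variance degenerate case: constant trace of the right length
  tr0 <- make_flight_tone_trace(600, 0, 60, rate_hz = 10, seed = 1)
  expect_equal(nrow(tr0), 600)
  expect_true(all(tr0$freq_hz == 600))

  # stationary moments: closed-form OU oracle. The variance of the time
  # average over T is ~ 2 sd^2 tau / T, giving the SE used below.
  tr <- make_flight_tone_trace(844, 55, 600, rate_hz = 10,
                               reversion_time_s = 5, seed = 7)
  se_mean <- 55 * sqrt(2 * 5 / 600)
  expect_lt(abs(mean(tr$freq_hz) - 844), 3 * se_mean)
  expect_lt(abs(sd(tr$freq_hz) - 55) / 55, 0.10)
})

test_that("trace generation is seed-deterministic", {
  a <- make_flight_tone_trace(844, 55, 10, seed = 1)
  b <- make_flight_tone_trace(844, 55, 10, seed = 1)
  c <- make_flight_tone_trace(844, 55, 10, seed = 2)
  expect_identical(a$freq_hz, b$freq_hz)
  expect_false(identical(a$freq_hz, c$freq_hz))
  expect_error(make_flight_tone_trace(844, 55, -1), "duration")
  expect_error(make_flight_tone_trace(844, 55, 10, rate_hz = 0), "rate")
})

test_that("cage audio matches its ground truth under a spectral oracle", {
  pop <- phonotype_population(3, "male", within_sd_hz = 0, seed = 3)
  cfg <- cage_sim_config(duration_s = 20,
                         flyby_rate_per_min = c(baseline = 0, swarming = 9,
                                                activated = 0),
                         seed = 11)
  cage <- synth_cage_audio(pop, cfg, start_zt_h = 13)
  gt <- cage$ground_truth
  expect_gt(nrow(gt), 0)
  # events non-overlapping and inside the recording
  expect_true(all(diff(gt$start_s) > 0))
  expect_true(all(gt$end_s[-nrow(gt)] <= gt$start_s[-1]))
  expect_true(all(gt$end_s <= 20))
  # every inserted event is recoverable by an independent FFT oracle
  for (i in seq_len(nrow(gt))) {
    seg <- cage$samples[(round(gt$start_s[i] * 50000) + 1):
                          round(gt$end_s[i] * 50000)]
    expect_lt(abs(fft_peak_hz(seg, 50000) - gt$freq_hz[i]), 2)
  }
})

test_that("pure background and noise-burst-only recordings are labelled", {
  pop <- phonotype_population(2, "male", seed = 1)
  cfg0 <- cage_sim_config(duration_s = 5,
                          flyby_rate_per_min = c(baseline = 0, swarming = 0,
                                                 activated = 0),
                          seed = 5)
  cage0 <- synth_cage_audio(pop, cfg0)
  expect_equal(nrow(cage0$ground_truth), 0)
  expect_lt(sd(cage0$samples), 2 * cfg0$background_rms)

  cfgn <- cage_sim_config(duration_s = 30,
                          flyby_rate_per_min = c(baseline = 0, swarming = 0,
                                                 activated = 0),
                          noise_burst = list(rate_per_min = 20), seed = 6)
  cagen <- synth_cage_audio(pop, cfgn)
  gt <- cagen$ground_truth
  expect_gt(nrow(gt), 0)
  expect_true(all(gt$kind == "noise"))
  expect_equal(gt$end_s - gt$start_s, rep(0.03, nrow(gt)))
  expect_true(all(abs(gt$freq_hz - 653) < 5 * 3.7))

  expect_error(synth_cage_audio(pop[0, ],
                                cage_sim_config(duration_s = 1, seed = 1)),
               "population")
})

test_that("actogram bouts are placed by the entrainment/free-run rule", {
  # entrained: identical onset every day
  a24 <- synth_actogram(period_h = 24, days = 3, seed = 1)
  gt <- attr(a24, "ground_truth")
  expect_equal(gt$onset_zt_h, rep(13, 3))

  # free-running at 22.5 h: onsets advance 1.5 h per day
  afr <- synth_actogram(period_h = 22.5, days = 3, entrained_days = 1,
                        seed = 1)
  gt <- attr(afr, "ground_truth")
  expect_equal(diff(gt$onset_zt_h), c(-1.5, -1.5))

  expect_error(synth_actogram(period_h = 0, days = 3), "period")
  expect_error(synth_actogram(days = 0), "days")
  # determinism
  expect_identical(synth_actogram(days = 2, seed = 9)$counts,
                   synth_actogram(days = 2, seed = 9)$counts)
})
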