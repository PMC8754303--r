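test_that("percent moving is a bounded, scale-free group fraction", {
  zero <- activity_series(matrix(0L, 100, 5))
  expect_true(all(percent_moving(zero)$fraction == 0))
  busy <- activity_series(matrix(3L, 100, 5))
  expect_true(all(percent_moving(busy)$fraction == 1))

  act <- synth_actogram(days = 1, n_tubes = 10, bout_rate = 8,
                        noise_rate = 0, seed = 1)
  pm <- percent_moving(act, window_min = 5)
  gt <- attr(act, "ground_truth")
  in_bout <- pm$zt_h >= gt$onset_zt_h & pm$zt_h < gt$onset_zt_h + 0.5
  expect_gt(mean(pm$fraction[in_bout]), 10 * mean(pm$fraction[!in_bout]))
  # scale-free: multiplying counts changes nothing
  act2 <- act; act2$counts <- act$counts * 7L
  expect_equal(percent_moving(act2), pm)
})

test_that("peak activity times follow the low-pass argmax rule", {
  # rectangular bout ZT13-13.5: symmetric filter argmax at the centre
  counts <- integer(1440)
  counts[(13 * 60 + 1):(13.5 * 60)] <- 5L
  act <- activity_series(counts)
  pk <- peak_activity_time(act)
  expect_equal(pk$peak_zt_h, 13.25, tolerance = 0.02)

  # two equal bouts: the earliest is returned (documented tie rule)
  counts2 <- integer(1440)
  counts2[301:330] <- 4L
  counts2[901:930] <- 4L
  expect_lt(peak_activity_time(activity_series(counts2))$peak_zt_h, 6)

  # a 1-min offset between two series is recovered to bin precision
  mk <- function(onset_min, seed) {
    counts <- rep(0.05, 1440)
    counts[onset_min:(onset_min + 30)] <- 6
    set.seed(seed)
    activity_series(rpois(1440, counts))
  }
  d <- replicate(20, {
    s <- sample.int(1e6, 1)
    peak_activity_time(mk(781, s))$peak_zt_h -
      peak_activity_time(mk(780, s + 1))$peak_zt_h
  })
  expect_lt(abs(mean(d) * 60 - 1), 1.5)
})

test_that("chi-square periodogram recovers generated periods", {
  # noise-free 24-h square wave
  counts <- rep(rep(c(0L, 5L), c(1380, 60)), 4)
  est <- chi_square_periodogram(activity_series(counts))
  expect_equal(est$period_h, 24, tolerance = 0.1)

  # generator recovery across periods, 20 seeds each
  for (p in c(22.0, 22.64, 23.5, 24.0)) {
    ests <- vapply(1:20, function(s) {
      act <- synth_actogram(period_h = p, days = 5, entrained_days = 0,
                            noise_rate = 0.1, seed = s)
      chi_square_periodogram(act)$period_h
    }, numeric(1))
    expect_true(all(abs(ests - p) <= 0.1),
                label = sprintf("period %.2f recovered", p))
  }

  # pure white noise: nothing above the significance line
  set.seed(99)
  noise <- activity_series(matrix(rpois(1440 * 5, 1), ncol = 1))
  expect_true(is.na(chi_square_periodogram(noise)$period_h))

  expect_error(
    chi_square_periodogram(activity_series(matrix(1L, 100, 1))),
    "shorter")
})

test_that("flyby activity and phonotaxis index summarize event tables", {
  empty <- data.frame(zt_h = numeric(0), start_s = numeric(0))
  fa <- flyby_activity(empty, zt_range = c(12, 14))
  expect_true(all(fa$events_per_min == 0))

  # uniform rate r -> flat series at r
  ev <- data.frame(zt_h = 12 + rep(0:59, each = 3) / 60 + 0.001,
                   start_s = 0)
  fa2 <- flyby_activity(ev, window_min = 5, zt_range = c(12, 13))
  mid <- fa2$events_per_min[10:50]
  expect_true(all(abs(mid - 3) < 1e-9))

  # phonotaxis: all events during playback -> 1; uniform -> ~1/30;
  # empty interval -> NA (undefined, not 0)
  iv <- data.frame(interval_start_s = c(0, 1800, 3600),
                   interval_end_s = c(1800, 3600, 5400),
                   playback_start_s = c(0, 1800, 3600),
                   playback_end_s = c(60, 1860, 3660))
  ev2 <- data.frame(start_s = c(10, 50, 1800 + seq(0, 1799, by = 60)))
  px <- phonotaxis_index(ev2, iv)
  expect_equal(px$index[1], 1)
  expect_equal(px$index[2], 1 / 30)
  expect_true(is.na(px$index[3]))
})
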