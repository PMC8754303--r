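const_pair <- function(fm, ff, dur_s = 60, rate = 10) {
  n <- dur_s * rate
  t <- (seq_len(n) - 1) / rate
  pair_trace(flight_tone_trace(t, rep(fm, n), rate_hz = rate),
             flight_tone_trace(t, rep(ff, n), rate_hz = rate))
}

ou_pair <- function(seed, dur_s = 60, mu_m = 900, mu_f = 600,
                    sd_m = 20, sd_f = 15) {
  pair_trace(make_flight_tone_trace(mu_m, sd_m, dur_s, seed = seed),
             make_flight_tone_trace(mu_f, sd_f, dur_s, seed = seed + 1e5))
}

test_that("convergence events are threshold runs on the harmonic distance", {
  # male 900 / female 600 at (2,3): |1800 - 1800| = 0, one full-trace event
  ev <- detect_hc_events(const_pair(900, 600))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 0)
  expect_equal(ev$end_s, 60)

  # male 880: |1760 - 1800| = 40 > 20 -> nothing
  cfg20 <- hc_config(tol_hz = 20)
  expect_equal(nrow(detect_hc_events(const_pair(880, 600), cfg20)), 0)

  expect_error(pair_trace(make_flight_tone_trace(900, 0, 10),
                          make_flight_tone_trace(600, 0, 20)),
               "equal length")
})

test_that("detector equals the brute-force run-length oracle", {
  cfg <- hc_config(tol_hz = 30, min_dur_s = 0.5)
  for (s in 1:30) {
    p <- ou_pair(s)
    expect_equal(nrow(detect_hc_events(p, cfg)), bf_hc_count(p, cfg),
                 label = sprintf("seed %d", s))
  }
})

test_that("distance to ratio is the mean absolute instantaneous deviation", {
  expect_equal(distance_to_ratio(const_pair(900, 600)), 0)
  expect_equal(distance_to_ratio(const_pair(960, 600)), 0.1)
  p <- ou_pair(42)
  expect_equal(distance_to_ratio(p),
               mean(abs(p$male$freq_hz / p$female$freq_hz - 1.5)))
})

test_that("virtual pairs are seeded draws without repeated combinations", {
  males <- synth_trace_pool(3, 900, seed = 1, duration_s = 5)
  females <- synth_trace_pool(3, 600, seed = 2, duration_s = 5)
  all9 <- build_virtual_pairs(males, females, 9, seed = 3)
  expect_equal(length(all9), 9)
  combos <- vapply(all9, function(p)
    paste(p$male$freq_hz[1], p$female$freq_hz[1]), character(1))
  expect_equal(length(unique(combos)), 9)
  expect_error(build_virtual_pairs(males, females, 10), "combinations")

  again <- build_virtual_pairs(males, females, 5, seed = 7)
  once <- build_virtual_pairs(males, females, 5, seed = 7)
  expect_identical(vapply(again, function(p) p$male$freq_hz[1], numeric(1)),
                   vapply(once, function(p) p$male$freq_hz[1], numeric(1)))

  # pools sized to yield 513 pairs, as in the published virtual-pair null
  m27 <- synth_trace_pool(27, 900, seed = 4, duration_s = 2)
  f19 <- synth_trace_pool(19, 600, seed = 5, duration_s = 2)
  expect_equal(length(build_virtual_pairs(m27, f19, 513, seed = 6)), 513)
})

test_that("null count distributions and thresholds behave", {
  # all pairs at the exact ratio: degenerate null at N = 1
  pairs1 <- replicate(10, const_pair(900, 600), simplify = FALSE)
  null1 <- null_count_distribution(pairs1)
  expect_true(all(null1$counts == 1))
  # all pairs far from the ratio: degenerate at N = 0
  pairs0 <- replicate(10, const_pair(700, 600), simplify = FALSE)
  expect_true(all(null_count_distribution(pairs0)$counts == 0))

  # lone vs live labels drawn from the same generative world are
  # exchangeable: a rank-sum test finds nothing (no interaction exists
  # by construction)
  pools <- hc_pools(15, 15, seed = 11)
  lone <- build_virtual_pairs(pools$males, pools$females, 50, seed = 12)
  pools2 <- hc_pools(15, 15, seed = 13)
  live <- build_virtual_pairs(pools2$males, pools2$females, 50, seed = 14)
  cfg <- hc_config(tol_hz = 20, min_dur_s = 0.5)
  n_lone <- null_count_distribution(lone, cfg)$counts
  n_live <- null_count_distribution(live, cfg)$counts
  expect_gt(suppressWarnings(wilcox.test(n_lone, n_live))$p.value, 0.01)
})

test_that("circular phase scans expose (or refute) real-time coupling", {
  # perfectly coupled pair: male = 1.5 x female pointwise; the zero-shift
  # count is strictly maximal
  f <- make_flight_tone_trace(600, 30, 60, reversion_time_s = 2, seed = 21)
  m <- flight_tone_trace(f$time_s, 1.5 * f$freq_hz, rate_hz = 10)
  sc <- circular_phase_scan(pair_trace(m, f), n_shifts = 60)
  expect_equal(sc$n_events[1], 1)
  expect_true(all(sc$n_events[-1] < sc$n_events[1]))

  # constant pair: counts identical at every shift
  scc <- circular_phase_scan(const_pair(900, 600), n_shifts = 30)
  expect_true(all(scc$n_events == scc$n_events[1]))

  # total event mass over all shifts is invariant under relabeling of
  # the trace origin (circularity conservation)
  p <- ou_pair(31)
  rotate <- function(tr, k) {
    n <- nrow(tr)
    flight_tone_trace(tr$time_s, tr$freq_hz[c((k + 1):n, seq_len(k))],
                      rate_hz = attr(tr, "rate_hz"))
  }
  cfg <- hc_config(tol_hz = 30, min_dur_s = 0.5)
  s1 <- circular_phase_scan(p, config = cfg)
  p_rot <- pair_trace(rotate(p$male, 100), rotate(p$female, 100))
  s2 <- circular_phase_scan(p_rot, config = cfg)
  expect_equal(sort(s1$n_events), sort(s2$n_events))

  expect_error(circular_phase_scan(p, n_shifts = 1e6), "exceeds")
})

test_that("cohort comparison finds no difference between identical worlds", {
  pools <- hc_pools(12, 12, seed = 41)
  live <- build_virtual_pairs(pools$males, pools$females, 30, seed = 42)
  res_same <- compare_cohorts(list(live = live, lone = live), seed = 43)
  expect_equal(res_same$summary$median_n[1], res_same$summary$median_n[2])
  expect_equal(res_same$tone_tests$statistic, 0)
  expect_gt(res_same$count_tests$p_value, 0.99)

  # distinct male states: the flight-tone test fires, and the cohort
  # closer to ratio 1.5 (at female 600: male 900) converges more
  lo_pool <- synth_trace_pool(12, 751, between_sd_hz = 20,
                              within_sd_hz = 15, seed = 44)
  hi_pool <- synth_trace_pool(12, 900, between_sd_hz = 20,
                              within_sd_hz = 15, seed = 45)
  fem <- synth_trace_pool(12, 600, between_sd_hz = 15, within_sd_hz = 10,
                          seed = 46)
  lo <- build_virtual_pairs(lo_pool, fem, 40, seed = 47)
  hi <- build_virtual_pairs(hi_pool, fem, 40, seed = 48)
  cfg <- hc_config(tol_hz = 20, min_dur_s = 0.5)
  res <- compare_cohorts(list(baseline = lo, swarm = hi), cfg, seed = 49)
  expect_lt(res$tone_tests$p_value, 1e-6)
  d_lo <- mean(vapply(lo, distance_to_ratio, numeric(1)))
  d_hi <- mean(vapply(hi, distance_to_ratio, numeric(1)))
  expect_lt(d_hi, d_lo)
  m_lo <- res$summary$median_n[res$summary$cohort == "baseline"]
  m_hi <- res$summary$median_n[res$summary$cohort == "swarm"]
  expect_gte(m_hi, m_lo)
})

test_that("convergence counts anti-correlate with distance to the ratio", {
  pools <- hc_pools(20, 20, seed = 51)
  pairs <- build_virtual_pairs(pools$males, pools$females, 150, seed = 52)
  cfg <- hc_config(tol_hz = 20, min_dur_s = 0.5)
  n <- vapply(pairs, function(p) nrow(detect_hc_events(p, cfg)), integer(1))
  d <- vapply(pairs, distance_to_ratio, numeric(1))
  expect_lt(cor(n, d, method = "spearman"), -0.2)
})
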