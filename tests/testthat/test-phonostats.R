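test_that("swarm window partition uses the closed ZT13 +/- 30 min rule", {
  ev <- data.frame(zt_h = c(13.0, 12.49, 12.5, 13.5, 13.51, 2.0))
  ph <- phase_split(ev)
  expect_equal(ph$phase,
               c("swarm", "other", "swarm", "swarm", "other", "other"))
  # wrap-around window
  ph0 <- phase_split(data.frame(zt_h = c(23.8, 0.2, 1.0)),
                     swarm_center_zt = 0)
  expect_equal(ph0$phase, c("swarm", "swarm", "other"))
})

test_that("Welch t is self-consistent between raw and summary inputs", {
  set.seed(1)
  a <- rnorm(80, 844, 55); b <- rnorm(40, 751, 80)
  raw <- welch_t(a, b)
  summ <- welch_t(c(mean = mean(a), sd = sd(a), n = length(a)),
                  c(mean = mean(b), sd = sd(b), n = length(b)))
  expect_equal(raw$statistic, summ$statistic)
  expect_equal(raw$df, summ$df)
  expect_equal(raw$cohens_d, summ$cohens_d)
  # agreement with the reference implementation
  ref <- t.test(a, b)
  expect_equal(raw$statistic, unname(ref$statistic))
  expect_equal(raw$p_value, ref$p.value)

  ident <- welch_t(a, a)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_equal(ident$cohens_d, 0)
})

test_that("the published male swarm contrast gives a huge effect size", {
  # printed cohort summaries: 844/55/1600 vs 751/80/445; d from these
  # rounded inputs is 1.52 (1.53 printed from unrounded data)
  res <- welch_t(c(mean = 844, sd = 55, n = 1600),
                 c(mean = 751, sd = 80, n = 445))
  expect_equal(res$mean_diff, 93)
  expect_equal(round(res$cohens_d, 2), 1.52)
  expect_lt(res$p_value, 1e-80)
  expect_gt(res$statistic, 20)
})

test_that("effect-size estimation is calibrated on known separations", {
  set.seed(2)
  ds <- replicate(100, {
    welch_t(rnorm(1000, 1, 1), rnorm(1000, 0, 1))$cohens_d
  })
  expect_gt(mean(ds > 0.9 & ds < 1.1), 0.9)
})

test_that("one-way ANOVA separates phonotypes and flags degeneracy", {
  # constant groups: no within variance, flagged
  deg <- anova_individuals(rep(c(600, 610, 620), each = 5),
                           rep(1:3, each = 5))
  expect_true(deg$degenerate)

  # 18 phonotypes, between-SD 30 Hz, within-SD 15 Hz: overwhelming F
  set.seed(3)
  means <- rnorm(18, 607, 30)
  tones <- unlist(lapply(means, function(m) rnorm(30, m, 15)))
  ids <- rep(seq_len(18), each = 30)
  res <- anova_individuals(tones, ids)
  expect_false(res$degenerate)
  expect_lt(res$p_value, 1e-10)
  expect_error(anova_individuals(1:5, rep(1, 5)), "individuals")
})

test_that("phonotype summaries weight each detected flyby equally", {
  ev <- data.frame(individual_id = rep(c("M1", "M2"), each = 4),
                   median_freq_hz = c(900, 910, 880, 890, 850, 855, 845, 860),
                   zt_h = rep(c(13.0, 13.2, 5, 6), 2))
  ps <- phonotype_summary(ev)
  expect_equal(ps$swarm_mean_hz, c(905, 852.5))
  expect_equal(ps$other_mean_hz, c(885, 852.5))
  expect_equal(ps$swarm_n, c(2, 2))
})

test_that("audibility matrix ranks females by distance to the 1.5 ratio", {
  # exact match -> 1; rank order follows |mean ratio - 1.5|
  set.seed(4)
  male <- list(M1 = rnorm(300, 900, 25))
  females <- list(F1 = rnorm(300, 500, 25),   # ratio 1.80
                  F2 = rnorm(300, 560, 25),   # ratio 1.61
                  F3 = rnorm(300, 600, 25))   # ratio 1.50
  amat <- audibility_matrix(male, females)
  expect_true(all(amat >= 0 & amat <= 1))
  expect_equal(order(amat[1, ]), order(-abs(attr(amat, "mean_ratio")[1, ]
                                            - 1.5)))
  expect_gt(amat["M1", "F3"], amat["M1", "F2"])

  cm <- audibility_matrix(list(A = rep(750, 50)), list(B = rep(500, 50)))
  expect_equal(cm[1, 1], 1)

  # permutation equivariance: relabeling reorders rows/cols only
  m2 <- list(Ma = male$M1, Mb = rnorm(300, 840, 25))
  am <- audibility_matrix(m2, females)
  am_sw <- audibility_matrix(m2[c(2, 1)], females[c(3, 1, 2)])
  expect_equal(am_sw, am[c(2, 1), c(3, 1, 2)],
               ignore_attr = TRUE)
})
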