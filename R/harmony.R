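#' Pair two flight-tone traces
#'
#' @param male,female `flight_tone_trace` objects with equal sampling rate
#'   and length.
#' @param pairing One of `"live"`, `"lone"` (virtual), `"playback"`.
#' @return A `pair_trace` list.
#' @export
pair_trace <- function(male, female,
                       pairing = c("live", "lone", "playback")) {
  pairing <- match.arg(pairing)
  if (nrow(male) != nrow(female))
    stop_invalid("male and female traces must have equal length (%d vs %d)",
                 nrow(male), nrow(female))
  rm_ <- attr(male, "rate_hz"); rf <- attr(female, "rate_hz")
  if (is.finite(rm_) && is.finite(rf) && abs(rm_ - rf) > 1e-9)
    stop_invalid("traces must share a sampling rate")
  structure(list(male = male, female = female, pairing = pairing,
                 rate_hz = rm_), class = "pair_trace")
}

#' Harmonic-convergence detection settings
#'
#' @param harmonic_pair `(m, n)`: male harmonic `m` matched against female
#'   harmonic `n`; the canonical convergence is male 2nd = female 3rd,
#'   i.e. a fundamental ratio of 3:2.
#' @param tol_hz Convergence tolerance at the harmonic level (Hz),
#'   absolute mode.
#' @param relative Use a relative criterion
#'   `|m*f_m / (n*f_f) - 1| <= tol_rel` instead of the absolute one.
#' @param tol_rel Relative tolerance (used when `relative = TRUE`).
#' @param min_dur_s Minimum event duration (s); convergence events are
#'   transient, of order 1-2 s.
#' @param max_dur_s Optional maximum duration (s), `Inf` for none.
#' @return An `hc_config` list.
#' @export
hc_config <- function(harmonic_pair = c(2, 3), tol_hz = 10,
                      relative = FALSE, tol_rel = 0.01,
                      min_dur_s = 1, max_dur_s = Inf) {
  structure(list(harmonic_pair = harmonic_pair, tol_hz = tol_hz,
                 relative = relative, tol_rel = tol_rel,
                 min_dur_s = min_dur_s, max_dur_s = max_dur_s),
            class = "hc_config")
}

# Interpolate NA dropouts up to max_gap_s; longer gaps stay NA (samples in
# them can never satisfy the convergence criterion).
fill_trace_gaps <- function(freq, rate_hz, max_gap_s = 0.5) {
  if (!anyNA(freq)) return(freq)
  idx <- seq_along(freq)
  ok <- !is.na(freq)
  if (sum(ok) < 2L) return(freq)
  filled <- approx(idx[ok], freq[ok], xout = idx, rule = 2)$y
  gaps <- true_runs(!ok)
  for (i in seq_len(nrow(gaps))) {
    if ((gaps$end[i] - gaps$start[i] + 1L) / rate_hz > max_gap_s)
      filled[gaps$start[i]:gaps$end[i]] <- NA_real_
  }
  filled
}

#' Detect harmonic-convergence events in a paired trace
#'
#' A convergence event is a maximal run of samples where the chosen male
#' harmonic matches the chosen female harmonic within tolerance
#' (`|m*f_male(t) - n*f_female(t)| <= tol_hz`, or the relative criterion),
#' lasting at least `min_dur_s`. Trace dropouts are linearly interpolated
#' up to 0.5-s gaps; longer gaps split events.
#'
#' @param pair A `pair_trace`.
#' @param config An [hc_config()].
#' @param circular Treat the trace as a circle: a run touching both ends
#'   wraps around and counts once. Used by [circular_phase_scan()], where
#'   the traces are glued into circles and no sample is an origin.
#' @return data.frame of events: `start_s`, `end_s`, `max_dev_hz` (largest
#'   harmonic-level deviation inside the event). For a wrapped event,
#'   `end_s` exceeds the trace duration by the wrapped part.
#' @export
detect_hc_events <- function(pair, config = hc_config(),
                             circular = FALSE) {
  stopifnot(inherits(pair, "pair_trace"))
  rate <- pair$rate_hz
  fm <- fill_trace_gaps(pair$male$freq_hz, rate)
  ff <- fill_trace_gaps(pair$female$freq_hz, rate)
  m <- config$harmonic_pair[1]; nh <- config$harmonic_pair[2]
  dev <- m * fm - nh * ff
  inside <- if (config$relative) {
    abs(m * fm / (nh * ff) - 1) <= config$tol_rel
  } else {
    abs(dev) <= config$tol_hz
  }
  inside[is.na(inside)] <- FALSE
  runs <- true_runs(inside)
  n_samp <- length(inside)
  wrap <- rep(FALSE, nrow(runs))
  if (circular && nrow(runs) > 1L &&
      runs$start[1L] == 1L && runs$end[nrow(runs)] == n_samp) {
    # the run crossing the glue point is one event
    runs$end[nrow(runs)] <- n_samp + (runs$end[1L] - runs$start[1L] + 1L)
    wrap[nrow(runs)] <- TRUE
    runs <- runs[-1L, , drop = FALSE]
    wrap <- wrap[-1L]
  }
  if (!nrow(runs))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      max_dev_hz = numeric(0)))
  dur <- (runs$end - runs$start + 1L) / rate
  keep <- dur >= config$min_dur_s & dur <= config$max_dur_s
  runs <- runs[keep, , drop = FALSE]
  wrap <- wrap[keep]
  dev_idx <- function(i) {
    idx <- runs$start[i]:runs$end[i]
    ((idx - 1L) %% n_samp) + 1L
  }
  data.frame(
    start_s = pair$male$time_s[runs$start],
    end_s = pair$male$time_s[1L] + runs$end / rate,
    max_dev_hz = vapply(seq_len(nrow(runs)), function(i)
      max(abs(dev[dev_idx(i)]), na.rm = TRUE), numeric(1)))
}

#' Mean absolute distance of instantaneous ratios from a harmonic ratio
#'
#' `d = mean_t | f_male(t) / f_female(t) - ratio |` over the flight. The
#' number of convergence events of a pair is a sharply decreasing function
#' of `d`: pairs whose tones are accidentally close to the ratio converge
#' by chance, pairs far from it never do.
#'
#' @param pair A `pair_trace`.
#' @param ratio Target fundamental ratio (3/2 for the canonical male-2nd =
#'   female-3rd convergence).
#' @return Non-negative scalar `d` (ratio units).
#' @export
distance_to_ratio <- function(pair, ratio = 3 / 2) {
  stopifnot(inherits(pair, "pair_trace"))
  r <- pair$male$freq_hz / pair$female$freq_hz
  mean(abs(r - ratio), na.rm = TRUE)
}

#' Assemble virtual ("lone") pairs from pools of lone-flying traces
#'
#' Draws seeded random male x female pairings without repeating a
#' combination. Because members of a virtual pair never flew together,
#' virtual pairs carry no interaction by construction: their convergence
#' counts form the chance reference (null) distribution.
#'
#' @param lone_males,lone_females Lists of `flight_tone_trace`.
#' @param n_pairs Number of pairs (at most `n_males * n_females`).
#' @param seed Integer seed.
#' @return List of `pair_trace` with pairing `"lone"`.
#' @export
build_virtual_pairs <- function(lone_males, lone_females, n_pairs,
                                seed = NULL) {
  nm <- length(lone_males); nf <- length(lone_females)
  if (n_pairs > nm * nf)
    stop_invalid("n_pairs (%d) exceeds available combinations (%d)",
                 n_pairs, nm * nf)
  combo <- with_seed(seed, sample.int(nm * nf, n_pairs))
  lapply(combo, function(k) {
    i <- ((k - 1L) %% nm) + 1L
    j <- ((k - 1L) %/% nm) + 1L
    pair_trace(lone_males[[i]], lone_females[[j]], pairing = "lone")
  })
}

#' Null distribution of convergence counts over a set of pairs
#'
#' Counts convergence events for each pair and summarizes the empirical
#' distribution of counts `N`. The significance threshold is the smallest
#' `N*` whose right-tail probability under the empirical null is below
#' `alpha`: a live pair must reach `N*` events before its count is
#' distinguishable from chance.
#'
#' @param pairs List of `pair_trace` (typically virtual pairs).
#' @param config An [hc_config()].
#' @param alpha Right-tail significance level.
#' @return List of class `hc_null`: `counts` (per pair), `table`
#'   (empirical distribution), `threshold` (`N*`, `Inf` if never reached),
#'   `alpha`.
#' @export
null_count_distribution <- function(pairs, config = hc_config(),
                                    alpha = 0.05) {
  counts <- vapply(pairs, function(p) nrow(detect_hc_events(p, config)),
                   integer(1))
  tab <- table(factor(counts, levels = 0:max(c(counts, 0L))))
  # right-tail P(N >= k) under the empirical distribution
  ks <- 0:(max(counts) + 1L)
  tail_p <- vapply(ks, function(k) mean(counts >= k), numeric(1))
  hit <- which(tail_p < alpha)
  threshold <- if (length(hit)) ks[hit[1L]] else Inf
  structure(list(counts = counts, table = tab, threshold = threshold,
                 alpha = alpha), class = "hc_null")
}

#' P-value of an observed convergence count against a null
#'
#' @param n_obs Observed event count.
#' @param null An `hc_null`.
#' @return Right-tail probability `P(N >= n_obs)` under the empirical
#'   null.
#' @export
hc_p_value <- function(n_obs, null) {
  stopifnot(inherits(null, "hc_null"))
  mean(null$counts >= n_obs)
}

#' Circular phase-shift scan of a pair
#'
#' The two 1-min traces are "circularized" by gluing their ends to their
#' beginnings; the female trace is then rotated against the male trace by
#' every multiple of `360 / n_shifts` degrees (realized as integer sample
#' rotations) and convergence events are counted at each shift. A phase
#' shift of 0 is the real-time pairing: if convergence reflected real-time
#' interaction, the zero-shift count should be maximal; if convergence is
#' chance, the zero-shift count is just one arbitrary draw among all
#' rotations and its rank is uniform.
#'
#' @param pair A `pair_trace`.
#' @param n_shifts Number of evenly spaced rotations (at most the trace
#'   length in samples; default the trace length).
#' @param config An [hc_config()].
#' @return data.frame `shift_deg`, `shift_samples`, `n_events`; row 1 is
#'   the unrotated pairing.
#' @export
circular_phase_scan <- function(pair, n_shifts = NULL,
                                config = hc_config()) {
  stopifnot(inherits(pair, "pair_trace"))
  len <- nrow(pair$male)
  if (is.null(n_shifts)) n_shifts <- len
  if (n_shifts > len)
    stop_invalid("n_shifts (%d) exceeds trace length (%d)", n_shifts, len)
  shifts <- round(seq(0, len, length.out = n_shifts + 1L)[-(n_shifts + 1L)])
  counts <- vapply(shifts, function(s) {
    ff <- pair$female
    if (s > 0) {
      rot <- c(ff$freq_hz[(s + 1L):len], ff$freq_hz[seq_len(s)])
      ff <- flight_tone_trace(ff$time_s, rot, rate_hz = attr(ff, "rate_hz"))
    }
    p2 <- pair_trace(pair$male, ff, pairing = pair$pairing)
    nrow(detect_hc_events(p2, config, circular = TRUE))
  }, integer(1))
  data.frame(shift_deg = shifts / len * 360, shift_samples = shifts,
             n_events = counts)
}

#' Randomized rank of the zero-shift convergence count
#'
#' Convergence counts are small integers with heavy ties; the rank of the
#' real-time (zero-shift) count within the scan is therefore computed as a
#' randomized probability integral transform: ties are broken uniformly,
#' which makes the rank exactly uniform on `(0, 1)` under exchangeability
#' of the shifts.
#'
#' @param scan data.frame from [circular_phase_scan()].
#' @param seed Optional seed for the tie-break.
#' @return Fractional rank in `(0, 1)`.
#' @export
scan_zero_rank <- function(scan, seed = NULL) {
  c0 <- scan$n_events[scan$shift_samples == 0][1]
  below <- sum(scan$n_events < c0)
  ties <- sum(scan$n_events == c0)
  u <- with_seed(seed, runif(1))
  (below + u * ties) / nrow(scan)
}

#' Compare convergence statistics across pairing cohorts
#'
#' Summarizes live, lone (virtual) and playback cohorts: median
#' convergence count with bootstrap SE per cohort, pairwise rank-sum tests
#' on counts, and Welch tests on median flight tones and trace variances
#' (testing the traces themselves for cohort differences).
#'
#' @param cohorts Named list of lists of `pair_trace` (e.g. `live`,
#'   `lone`, `playback`); empty cohorts are dropped.
#' @param config An [hc_config()].
#' @param n_boot Bootstrap replicates for the median SE.
#' @param seed Seed for the bootstrap.
#' @return List of class `hc_cohort_summary`: `summary` (per-cohort
#'   data.frame), `count_tests`, `tone_tests`, `var_tests` (pairwise
#'   data.frames).
#' @export
compare_cohorts <- function(cohorts, config = hc_config(), n_boot = 500,
                            seed = NULL) {
  cohorts <- cohorts[vapply(cohorts, length, integer(1)) > 0]
  stats_of <- function(pairs) {
    list(counts = vapply(pairs, function(p)
           nrow(detect_hc_events(p, config)), integer(1)),
         tones = vapply(pairs, function(p)
           median(p$male$freq_hz, na.rm = TRUE), numeric(1)),
         vars = vapply(pairs, function(p)
           var(p$male$freq_hz, na.rm = TRUE), numeric(1)))
  }
  st <- lapply(cohorts, stats_of)
  summ <- with_seed(seed, {
    do.call(rbind, lapply(names(st), function(nm) {
      x <- st[[nm]]$counts
      boot <- vapply(seq_len(n_boot), function(i)
        median(sample(x, replace = TRUE)), numeric(1))
      data.frame(cohort = nm, n_pairs = length(x),
                 median_n = median(x), se_median = sd(boot),
                 stringsAsFactors = FALSE)
    }))
  })
  pairwise <- function(field, test) {
    nms <- names(st)
    if (length(nms) < 2) return(data.frame())
    combs <- utils::combn(nms, 2)
    do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
      a <- st[[combs[1, j]]][[field]]; b <- st[[combs[2, j]]][[field]]
      res <- test(a, b)
      data.frame(cohort_a = combs[1, j], cohort_b = combs[2, j],
                 statistic = unname(res$statistic), p_value = res$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    summary = summ,
    count_tests = pairwise("counts", function(a, b)
      suppressWarnings(wilcox.test(a, b))),
    tone_tests = pairwise("tones", function(a, b) t.test(a, b)),
    var_tests = pairwise("vars", function(a, b) t.test(a, b))),
    class = "hc_cohort_summary")
}
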