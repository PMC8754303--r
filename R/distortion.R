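#' Quadratic and cubic distortion products of a two-tone stimulus
#'
#' A nonlinear receiver (the mosquito flagellar ear) stimulated with a
#' female tone `f1` and a male tone `f2` produces, among others, the
#' quadratic distortion product (difference tone) `f2 - f1` and the cubic
#' distortion product `2*f1 - f2`. Values are returned signed; audibility
#' scoring uses the absolute value (the physical distortion frequency).
#'
#' @param f1 Female fundamental(s) (Hz), positive.
#' @param f2 Male fundamental(s) (Hz), positive.
#' @return data.frame `quadratic`, `cubic` (Hz, signed). Vectors recycle as
#'   usual.
#' @export
#' @examples
#' distortion_products(500, 750)   # ratio 1.5: both at 0.5 * f1
distortion_products <- function(f1, f2) {
  if (any(f1 <= 0) || any(f2 <= 0))
    stop_invalid("fundamental frequencies must be positive")
  data.frame(quadratic = f2 - f1, cubic = 2 * f1 - f2)
}

#' The super-distortion optimum
#'
#' Solving `f2 - f1 = 2*f1 - f2` gives `f2/f1 = 3/2`: at a male/female
#' flight-tone ratio of exactly 1.5 the quadratic and cubic distortion
#' products coincide at `0.5 * f1`, summing into a single "super
#' distortion" — the theoretical optimum the male swarm-time frequency
#' increase targets. The ratio is independent of `f1`.
#'
#' @param f1 Female fundamental (Hz).
#' @return List with `ratio` (3/2) and `freq_hz` (`0.5 * f1`).
#' @export
superdistortion_optimum <- function(f1) {
  if (any(f1 <= 0)) stop_invalid("f1 must be positive")
  # f2 - f1 = 2 f1 - f2  =>  2 f2 = 3 f1
  ratio <- 3 / 2
  list(ratio = ratio, freq_hz = (ratio - 1) * f1)
}

#' Pairwise male/female ratio and distortion distributions
#'
#' Forms male x female tone pairs — the exhaustive Cartesian product when
#' its size is at most `max_pairs`, otherwise a seeded uniform subsample —
#' and returns the distortion products and fundamental ratios of every
#' pair. The Cartesian rule reproduces the pair counts of the published
#' cohort analyses (e.g. 1600 male x 3040 female tones = 4,864,000 pairs).
#'
#' @param males,females Numeric vectors of fundamental frequencies (Hz),
#'   `f2` and `f1` respectively.
#' @param max_pairs Largest exhaustive product; above this, `max_pairs`
#'   pairs are subsampled.
#' @param seed Seed for the subsample (unused when exhaustive).
#' @return A `distortion_set`: list with `quadratic`, `cubic`, `ratios`
#'   (vectors over pairs), `f1` (female tone of each pair), `n_pairs`,
#'   `exhaustive`, `mean_ratio`, `sd_ratio`.
#' @export
pair_ratio_distribution <- function(males, females, max_pairs = 1e7,
                                    seed = NULL) {
  if (!length(males) || !length(females))
    stop_invalid("both samples must be non-empty")
  n_full <- length(males) * length(females)
  if (n_full <= max_pairs) {
    f2 <- rep(males, times = length(females))
    f1 <- rep(females, each = length(males))
    exhaustive <- TRUE
  } else {
    idx <- with_seed(seed, {
      list(m = sample.int(length(males), max_pairs, replace = TRUE),
           f = sample.int(length(females), max_pairs, replace = TRUE))
    })
    f2 <- males[idx$m]; f1 <- females[idx$f]
    exhaustive <- FALSE
  }
  dp <- distortion_products(f1, f2)
  ratios <- f2 / f1
  structure(list(quadratic = dp$quadratic, cubic = dp$cubic,
                 ratios = ratios, f1 = f1,
                 n_pairs = length(ratios), exhaustive = exhaustive,
                 mean_ratio = mean(ratios), sd_ratio = sd(ratios)),
            class = "distortion_set")
}

#' Audibility overlap of the two distortion-product distributions
#'
#' Histogram-intersection coefficient `sum_bins min(p, q)` between the
#' normalized distributions of |quadratic| and |cubic| distortion
#' frequencies, computed over bins restricted to the nerve-sensitivity
#' window (optionally over all frequencies). 1 for identical
#' distributions, 0 for disjoint ones; symmetric and bounded in `[0, 1]`.
#' The overlap is maximal when the cohorts sit at the 1.5 ratio, where
#' both distortions coincide at `0.5 * f1`.
#'
#' @param dset A `distortion_set`.
#' @param window A [nerve_window()]; `NULL` disables windowing.
#' @param bin_hz Histogram bin width (Hz); results are stable for 1-10 Hz.
#' @param windowed Restrict to the nerve window (default) or use all
#'   frequencies.
#' @return Overlap fraction in `[0, 1]`.
#' @export
audibility_overlap <- function(dset, window = nerve_window(), bin_hz = 5,
                               windowed = TRUE) {
  stopifnot(inherits(dset, "distortion_set"))
  if (!is.finite(bin_hz) || bin_hz <= 0)
    stop_invalid("bin_hz must be positive")
  if (!dset$n_pairs) stop_invalid("empty distortion set")
  q <- abs(dset$quadratic); cb <- abs(dset$cubic)
  hi <- max(q, cb) + bin_hz
  breaks <- seq(0, hi + bin_hz, by = bin_hz)
  hq <- tabulate(findInterval(q, breaks), nbins = length(breaks))
  hc <- tabulate(findInterval(cb, breaks), nbins = length(breaks))
  # normalize over the full distribution, then restrict to the window:
  # out-of-window mass counts against the overlap (inaudible distortion)
  pq <- hq / sum(hq); pc <- hc / sum(hc)
  if (windowed && !is.null(window)) {
    centers <- breaks + bin_hz / 2
    keep <- centers >= window$lo_hz & centers <= window$hi_hz
    pq <- pq[keep]; pc <- pc[keep]
  }
  sum(pmin(pq, pc))
}
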