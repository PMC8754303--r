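---
title: "Flight-tone audibility and harmonic convergence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flight-tone audibility and harmonic convergence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmtone)
```

## The scientific problem

Malaria mosquitoes (*Anopheles gambiae*) mate in swarms that form at sunset
and last under half an hour. A male finds a female acoustically, by her
flight tone — yet his auditory nerve is nearly deaf to her actual wingbeat
frequency (~550 Hz): compound nerve responses are confined to roughly
65–400 Hz. Hearing works through *distortion products*: the nonlinear
mechanics of the flagellar ear, stimulated by the male's own tone $f_2$ and
a female tone $f_1$, produce components at the quadratic difference tone
$f_2 - f_1$ and the cubic distortion $2 f_1 - f_2$, which do fall inside
the nerve's response band. Setting

$$f_2 - f_1 = 2 f_1 - f_2 \iff \frac{f_2}{f_1} = \frac{3}{2},$$

both products coincide at $0.5\,f_1$ — a "super distortion" and the
theoretical audibility optimum. Males exploit it: around sunset they raise
their flight tones from a daytime baseline (~751 Hz at 28 °C) to a
swarming state (~844 Hz), moving the population ratio from 1.38 to 1.53,
and on hearing a female-like tone they shift further (~900 Hz, the
activated state). A byproduct of flying near the 3:2 ratio is that the
male's second harmonic transiently matches the female's third — "harmonic
convergence", previously read as acoustic communication. The package's
null machinery shows such events arise by chance from flight-tone variance
alone.

This package re-implements the full analysis chain as tested, reusable
code: flight-tone extraction from cage audio, circadian activity metrics,
distortion-product audibility scoring, and the harmonic-convergence null
statistics, plus a seeded synthetic-data module that emulates every input
so the whole chain runs without external recordings.

## The synthetic world

Every generator realizes conditions stated with the study's measurements;
where no value is printed, one realistic choice was made once and is
documented here.

* **Frequency walks.** No generative model for within-flight frequency
  variation is published. Traces are mean-reverting Gaussian
  (Ornstein–Uhlenbeck) walks, simulated with the exact discrete
  transition, so the stationary mean and SD equal the cohort parameters
  and excursions have a realistic 1–2 s scale. The reversion time
  (default 5 s) is a guess — the within-flight autocorrelation of real
  recordings is not reported — and is exposed in every generator.
* **Cohort parameters.** `cohort_params()` carries the measured
  means/SDs/sample sizes (28 °C: male swarm 844 ± 55 Hz *n* = 1600, male
  other 751 ± 80 Hz *n* = 445, female swarm 556 ± 40 Hz *n* = 3040,
  female other 547 ± 51 Hz *n* = 2339; 22 °C analogues; playback states).
  These are the defaults for ratio analyses and simulations.
* **Phonotypes.** Individuals occupy narrow bands: individual means are
  drawn around the population mean (between-individual SD ~30 Hz for
  males, matching the spread of individually housed animals) with a
  smaller within-flight SD (~15–20 Hz). This structure is what makes
  convergence counts vary across pairs.
* **Cage audio.** Flybys are multi-harmonic tones (relative amplitudes
  1/0.5/0.3/0.15 for harmonics 1–4 — only frequency ratios matter
  downstream) with 50-ms raised-cosine ramps, inserted at
  state-dependent Poisson rates over a Gaussian background at 50 kHz.
  Chamber noise bursts are 30-ms tones at 653 ± 3.7 Hz. Ground truth
  lists every inserted event.
* **Actograms.** Beam-break counts at 1-min bins: one 30-min dusk bout
  per day at ZT13 under entrainment; under free-running conditions the
  bout advances by $(24 - \tau)$ h/day ($\tau$ = 22.64 h for males,
  22.54 h for females), with Poisson background noise.

What a green test establishes is recovery of *this* stated world. Real
recordings add room acoustics, overlapping flybys, amplitude modulation
from flight paths, and non-Gaussian noise; none of these are emulated, so
detector performance on real audio is not certified by these tests.

## Numerical choices in the extraction pipeline

* **Band-pass.** "Fourth-order Butterworth" is implemented in the MATLAB
  convention (order-4 low-pass prototype, 8-pole band-pass), as a cascade
  of fourth-order sections for numerical stability at the narrow relative
  band (300–1200 Hz at 50 kHz), applied forward–backward. Zero-phase
  filtering squares the magnitude response, so stop-band attenuation at
  half/twice the corners exceeds 60 dB and corners sit at −6 dB.
* **Flyby detection.** The envelope is a 50-ms centered moving average of
  the rectified signal, compared against twice the rectified local mean
  (5-s span by default; the span is configurable and should be set to
  the whole segment for signals, like minute-long playback tones, that
  fill most of their segment). A centered moving average widens a burst
  by half the window on each side, so run bounds are contracted by that
  amount — event durations are then measured at the signal scale, which
  is what lets a >30 ms minimum-length rule reject the 30-ms chamber
  bursts. Runs closer than 50 ms are merged (envelope dropouts), events
  touching a 1-min chunk boundary are stitched.
* **Sinusoid fits.** The printed model $y = \sin(2\pi x t) + \cos(2\pi
  x t)$ has fixed unit amplitudes and cannot fit arbitrary signals; it is
  implemented with free coefficients $a \sin + b \cos$ (the $R^2$
  criterion implies as much), solved by linear least squares at each
  candidate $x$. The search localizes the periodogram peak, refines on a
  1-Hz grid, and finishes with parabolic interpolation, giving sub-Hz
  accuracy on clean tones across the whole band. Windows are 10 ms with
  50% slide; an event's flight tone is the median over windows with
  $R^2 > 0.9$, and events with no passing window are dropped.

## Circadian analysis

Peak activity times are the per-day argmax of the counts after a centered
moving average of width 31 min (the simplest filter consistent with
"low-pass > 30 min"; ties break to the earliest bin). The free-running
period is the argmax of the Sokolove–Bushell statistic
$Q_p = N \sum_h (M_h - \bar x)^2 / \sum_i (x_i - \bar x)^2$ over
candidate periods (scan 16–32 h, step 0.1 h, 10-min phase classes),
subject to exceeding the $\chi^2_{K-1}$ significance line with Bonferroni
correction across the scan; if nothing is significant the estimate is
`NA` rather than an arbitrary argmax.

```{r periodogram}
act <- synth_actogram(period_h = 22.64, days = 5, entrained_days = 0,
                      noise_rate = 0.1, seed = 1)
chi_square_periodogram(act)$period_h
```

## Audibility scoring

The "proportion of overlap" between the two distortion distributions is
not given a formula in the source; it is implemented as the histogram
intersection $\sum_b \min(p_b, q_b)$ between the normalized
distributions of $|f_2 - f_1|$ and $|2 f_1 - f_2|$ over 5-Hz bins
(stable for 1–10-Hz bins), restricted to the nerve window 65–400 Hz by
default (both windowed and unwindowed modes are provided, since the
original choice is unstated). Normalization happens before windowing, so
distortion mass falling outside the audible band counts against the
overlap. Negative distortion frequencies (pairs beyond ratio 2) enter by
absolute value — the physical distortion frequency.

```{r overlap}
set.seed(1)
swarm <- pair_ratio_distribution(rnorm(1600, 844, 55),
                                 rnorm(3040, 556, 40))
other <- pair_ratio_distribution(rnorm(445, 751, 80),
                                 rnorm(2339, 547, 51))
c(swarm = audibility_overlap(swarm), other = audibility_overlap(other))
```

## Harmonic-convergence null machinery

A convergence event at harmonic pair $(m, n) = (2, 3)$ is a maximal run
with $|m f_\mathrm{male}(t) - n f_\mathrm{female}(t)| \le$ `tol_hz`
lasting at least `min_dur_s`. The tolerance used in the original event
counting is not printed; the default here is 10 Hz at the harmonic level
with 1-s minimum duration, both configurable, and every conclusion the
package tests (oracle equivalence, rank uniformity, the negative
$N$–$d$ relationship, exchangeability of identically generated cohorts)
is robust to this choice. Both absolute and relative criteria are
implemented; absolute is the default. Trace dropouts are interpolated up
to 0.5-s gaps; longer gaps split events.

Design decisions worth recording:

* Virtual pairs are drawn **without replacement** of the male × female
  combination (whether the original 513 pairs were is unstated).
* In the circular phase-shift scan the traces are glued into circles, so
  run detection wraps: a run crossing the glue point is one event. This
  makes the multiset of counts over all shifts exactly invariant to
  relabeling of the trace origin, which is the conservation property the
  scan's logic rests on.
* Convergence counts are small integers with heavy ties, so the rank of
  the zero-shift count within a scan (`scan_zero_rank()`) is a
  randomized probability integral transform: ties are broken uniformly,
  making the rank exactly uniform under exchangeability. A deterministic
  midrank would cluster and fail any uniformity test for spurious
  reasons.
* The published re-analysis statistics of the external tethered-flight
  dataset (median counts 3/4/2 per minute for live/lone/playback pairs;
  the ≥9-event P < 0.05 threshold from 513 virtual pairs) describe that
  dataset and its unpublished tolerance settings; they are documented
  here but are not reproduction targets, since the data are external.
  The package reproduces the *properties* that analysis rests on.

```{r hc}
pools_m <- synth_trace_pool(10, 900, seed = 1)
pools_f <- synth_trace_pool(10, 600, between_sd_hz = 20,
                            within_sd_hz = 15, seed = 2)
pairs <- build_virtual_pairs(pools_m, pools_f, 30, seed = 3)
cfg <- hc_config(tol_hz = 20, min_dur_s = 0.5)
null <- null_count_distribution(pairs, cfg)
c(median_N = median(null$counts), threshold = null$threshold)
```

## Cohort statistics

`welch_t()` accepts raw samples or summary triples (mean, SD, n) and
reports Cohen's *d* with the $(n-1)$-weighted pooled SD. From the rounded
printed summaries the male swarm-vs-other contrast gives $d = 1.52$; the
published 1.53 comes from unrounded data, a rounding-level difference
that is asserted as such in the tests. Degenerate ANOVA inputs (zero
within-group variance) are flagged, not reported as spurious F values.
The swarm window is the closed interval ZT13 ± 30 min; inclusivity must
be fixed somewhere for reproducible partitions, and closed was chosen.
Per-individual means weight each detected flyby equally (whether the
original weighted by duration is unstated).

## Known limitations

* One mosquito per flyby: no source separation of overlapping flybys,
  no Doppler correction, no microphone directivity.
* The nerve window enters as a fixed parameter (65–400 Hz, plateau
  150–300 Hz); the electrophysiology that measured it is out of scope.
* Peak-time analysis reports per-nominal-day peaks; under free-running
  conditions the drift is visible across days rather than unwrapped into
  a single phase estimate.
* The four microphone channels of the original rig are processed
  independently (whether the original medianized across channels per
  event is unstated).
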