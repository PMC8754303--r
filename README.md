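# swarmtone

Analysis pipeline for the bioacoustics and chronobiology of mosquito
mating swarms.

Malaria mosquitoes (*Anopheles gambiae*) swarm for less than half an hour
at sunset, and males must detect the faint flight tones of the few
entering females. The male auditory nerve responds only to ~65–400 Hz —
well below any actual flight tone — so hearing works through distortion
products of the nonlinear flagellar ear: a female tone *f₁* and male tone
*f₂* generate the quadratic difference tone *f₂ − f₁* and the cubic
distortion *2f₁ − f₂*. Solving *f₂ − f₁ = 2f₁ − f₂* gives *f₂/f₁ = 3/2*,
where both products coincide at *0.5·f₁*: a "super distortion" and the
audibility optimum. Around sunset males raise their flight tones from a
~751 Hz baseline to a ~844 Hz swarming state (28 °C), lifting the
population male/female ratio from 1.38 to 1.53 — and the transient match
of male second and female third harmonics ("harmonic convergence") that
accompanies a 3:2 ratio falls out by chance, not communication.

The package implements, as tested and reusable code:

* **synth** — seeded generators for every input: mean-reverting (OU)
  flight-tone traces, multi-harmonic cage audio at 50 kHz with ground
  truth, phonotype populations, and free-running actograms.
* **tonepipe** — the extraction pipeline: DC removal, fourth-order
  Butterworth band-pass (300/1200 Hz; 600/1200 Hz in playback mode),
  relative-envelope flyby detection, sliding 10-ms sinusoid fits with an
  *R²* > 0.9 median per event.
* **rhythm** — percent-moving curves, low-pass peak-activity times,
  chi-square (Sokolove–Bushell) periodogram, flyby-rate activity and
  phonotaxis indices.
* **distortion** — distortion products, Cartesian male×female ratio
  distributions, histogram-intersection audibility overlap within the
  nerve window, and the 1.5-ratio optimum.
* **harmony** — harmonic-convergence detection, the distance-to-ratio
  statistic *d*, virtual-pair null distributions, and the circular
  phase-shift surrogate test.
* **phonostats** — phonotype summaries, Welch *t* with Cohen's *d*,
  one-way ANOVA across individuals, male×female audibility matrices.

## Worked example

Simulate a swarm-hour cage recording and extract flight tones:

```r
library(swarmtone)
pop  <- phonotype_population(5, "male", seed = 1)
cfg  <- cage_sim_config(duration_s = 30, seed = 2)
cage <- synth_cage_audio(pop, cfg, start_zt_h = 13)
run_pipeline(cage)
#>   channel     zt_h  start_s    end_s median_freq_hz n_valid_fits
#> 1     ch1 13.00094  3.40018  4.24000       906.9977          166
#> 2     ch1 13.00369 13.29910 13.64292       876.9521           67
#> 3     ch1 13.00716 25.79036 26.67304       821.3871          175
```

Three flybys are detected; each `median_freq_hz` is the median of all
10-ms sinusoid fits with *R²* > 0.9 and sits within a few Hz of the
generator's ground truth (903.5, 877.0, 823.6 Hz). Cohort-level
audibility from the published parameters:

```r
set.seed(1)
swarm <- pair_ratio_distribution(rnorm(1600, 844, 55), rnorm(3040, 556, 40))
other <- pair_ratio_distribution(rnorm(445, 751, 80),  rnorm(2339, 547, 51))
round(c(swarm$mean_ratio, other$mean_ratio), 2)
#> [1] 1.53 1.38
round(c(audibility_overlap(swarm), audibility_overlap(other)), 2)
#> [1] 0.76 0.49
```

The swarm-time cohorts sit at the 1.53 ratio and their distortion
products overlap far more within the 65–400 Hz nerve window — the
male-driven audibility boost.

## Analysis workflow

The numbered drivers under `analysis/` run the full study on synthetic
data and write tables to `results/analysis/`:

```sh
Rscript analysis/01_simulate.R    # cage audio, actograms, trace pools
Rscript analysis/02_tones.R       # flight-tone extraction vs ground truth
Rscript analysis/03_rhythm.R      # peak times, free-running periods
Rscript analysis/04_distortion.R  # ratio/overlap tables, optimum scan
Rscript analysis/05_harmony.R     # virtual-pair null, phase-shift test
Rscript analysis/06_phonotypes.R  # individual phonotypes, cohort tests
```

## Acceptance script

`scripts/acceptance.R` recomputes the analysis's headline numbers from
scratch through the installed package — the Monte-Carlo cohort ratio
means from the published (mean, SD, n) parameters, the distortion-algebra
optimum, the pipeline's recovery of the 550-Hz playback tone, and the
periodogram recovery of the 22.64-h male free-running period — and
writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
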