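Package: swarmtone
Title: Flight-Tone Audibility and Circadian Swarming Analysis for Mosquitoes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the acoustics and chronobiology of mosquito
    mating swarms. Extracts flight tones from cage audio recordings (band-pass
    filtering, envelope-based flyby detection, sliding sinusoid fits), computes
    circadian activity metrics (actograms, peak activity times, chi-square
    periodogram free-running periods), models distortion-product audibility of
    females to males around the 3:2 male/female flight-tone ratio, and provides
    null-model statistics (virtual pairs, circular phase-shift surrogates)
    showing that harmonic-convergence events arise by chance. A seeded
    synthetic-data module emulates cage recordings, flight-tone traces and
    beam-break actograms so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
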