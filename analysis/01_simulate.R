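#!/usr/bin/env Rscript
# Stage 1 — simulate the study's raw inputs.
#
# Generates (a) a swarm-hour cage recording from a male phonotype
# population, with a ground-truth event table; (b) male and female
# 8-day actograms (3 entrained + 5 free-running days at the measured
# free-running periods); (c) pools of 1-min lone-flight tone traces for
# the harmonic-convergence null analyses. Everything is seeded, so
# downstream stages are reproducible bit for bit.

suppressPackageStartupMessages(library(swarmtone))
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1001

# (a) cage audio around lights-off (ZT13): swarming males
pop <- phonotype_population(8, "male", seed = seed)
cfg <- cage_sim_config(duration_s = 60,
                       flyby_rate_per_min = c(baseline = 0.5, swarming = 8,
                                              activated = 0),
                       noise_burst = list(rate_per_min = 2),
                       seed = seed + 1)
cage <- synth_cage_audio(pop, cfg, start_zt_h = 13)
write_wav(cage$samples, cage$sample_rate, file.path(out, "cage_swarm.wav"),
          format = "float32")
write.csv(cage$ground_truth, file.path(out, "cage_swarm_truth.csv"),
          row.names = FALSE)
message(sprintf("cage recording: %d s, %d ground-truth events (%d flybys)",
                cfg$duration_s, nrow(cage$ground_truth),
                sum(cage$ground_truth$kind == "flyby")))

# (b) actograms: males free-run at 22.64 h, females at 22.54 h
for (sex in c("male", "female")) {
  per <- if (sex == "male") 22.64 else 22.54
  act <- synth_actogram(period_h = per, days = 8, entrained_days = 3,
                        n_tubes = 20, bout_rate = 4, noise_rate = 0.05,
                        startle = TRUE, seed = seed + match(sex, c("male",
                                                                  "female")))
  write_activity_csv(act, file.path(out, sprintf("actogram_%s.csv", sex)))
}
message("actograms written for both sexes (3 LD + 5 DD days)")

# (c) lone-flight trace pools with phonotype structure
males <- synth_trace_pool(27, 900, between_sd_hz = 30, within_sd_hz = 20,
                          seed = seed + 10)
females <- synth_trace_pool(19, 600, between_sd_hz = 20, within_sd_hz = 15,
                            seed = seed + 11)
dir.create(file.path(out, "traces"), showWarnings = FALSE)
for (i in seq_along(males))
  write_trace_csv(males[[i]], file.path(out, "traces",
                                        sprintf("lone_male_%02d.csv", i)))
for (i in seq_along(females))
  write_trace_csv(females[[i]], file.path(out, "traces",
                                          sprintf("lone_female_%02d.csv",
                                                  i)))
message(sprintf("trace pools: %d lone males, %d lone females (1-min, 10 Hz)",
                length(males), length(females)))
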