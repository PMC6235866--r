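#!/usr/bin/env Rscript
# Simulate the study's data structure: a behavioral session of two vowels
# roved across five F0s with probe (whispered) trials and correction trials,
# and a recorded population whose units multiplex stimulus features at
# distinct latencies — vowel early, F0 late — with some units carrying
# choice or accuracy signals and engagement-dependent suppression.
# Writes trials.csv and spikes.csv consumed by the later stages.

library(vowelconstancy)

seed <- 20
out_dir <- "results/simulation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

trials <- generate_trial_table(
  trials_per_condition = 20,
  feature_values = c(149, 200, 263, 330, 459),
  p_correct = 0.78, probe_rate = 0.12, seed = seed)

# population: vowel-early / F0-late multiplexing units, onset units that
# respond to sound regardless of identity, plus choice-tuned,
# accuracy-tuned and untuned units
population <- c(
  lapply(1:10, function(i) unit_tuning(10, kernels = list(
    list(feature = "vowel", latency = 0.02, duration = 0.12,
         gain = c(u = 40 + 4 * i, e = 10)),
    list(feature = "f0", latency = 0.28, duration = 0.15,
         gain = c(`149` = 45, `200` = 25, `263` = 10))))),
  lapply(1:6, function(i) unit_tuning(10, kernels = list(
    list(feature = "vowel", latency = 0.02, duration = 0.15,
         gain = c(u = 30, e = 30))))),
  lapply(1:4, function(i) unit_tuning(8, kernels = list(
    list(feature = "choice", latency = 0.35, duration = 0.25,
         gain = c(left = 40, right = 5))))),
  lapply(1:3, function(i) unit_tuning(8, kernels = list(
    list(feature = "correct", latency = 0.3, duration = 0.3,
         gain = c(`TRUE` = 30, `FALSE` = 5))))),
  lapply(1:5, function(i) unit_tuning(12))
)
names(population) <- sprintf("unit_%02d", seq_along(population))

spikes <- generate_dataset(population, trials, seed = seed + 1)

write_trials(trials, file.path(out_dir, "trials.csv"))
write_spikes(spikes, file.path(out_dir, "spikes.csv"))
write.csv(data.frame(seed = seed,
                     n_trials = nrow(trials),
                     n_units = length(population)),
          file.path(out_dir, "provenance.csv"), row.names = FALSE)

cat("Simulated", nrow(trials), "trials (",
    sum(trials$trial_type == "test"), "test,",
    sum(trials$trial_type == "probe"), "probe,",
    sum(trials$trial_type == "correction"), "correction ) and",
    length(population), "units;",
    nrow(spikes), "spikes ->", out_dir, "\n")
cat("Behavioral percent correct (analysis trials):",
    round(100 * mean(filter_analysis_trials(trials)$correct), 1), "\n")
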