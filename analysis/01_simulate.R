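#!/usr/bin/env Rscript

# Stage 1: simulate the multi-subject action-concept experiment.
#
# Generates the default design — 10 action classes, 24 stimuli per class,
# 50 subjects each watching all stimuli of half the classes (so every
# stimulus is seen by 25 subjects), 62 channels, 3 s epochs at 250 Hz with
# a 1 s pre-stimulus baseline — and records what the latent world looks
# like. A small subset is also written to the JSON container together with
# the montage CSV, as a portable sample of the format.

library(eegconsensus)

seed <- 1
out_dir <- "results/01_simulate"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(seed = seed)
world <- generate_world(cfg)
trials <- trial_table(world)

cat("Design:", cfg$n_classes, "classes x", cfg$n_stimuli_per_class,
    "stimuli;", cfg$n_subjects, "subjects;", nrow(trials), "trials\n")
cat("Subjects per stimulus:",
    paste(range(table(trials$stimulus_id)), collapse = "-"), "\n")

write.csv(trials, file.path(out_dir, "trial_table.csv"), row.names = FALSE)
write_montage_csv(make_montage(cfg$n_channels),
                  file.path(out_dir, "montage.csv"))

# a miniature dataset in the container format (full default design would be
# gigabytes of JSON; the config regenerates it bit-identically on demand)
mini <- generate_dataset(generator_config(
  n_classes = 2, classes_per_subject = 1, n_subjects = 4,
  n_stimuli_per_class = 3, n_channels = 8, n_samples = 250,
  pre_stimulus_samples = 50, seed = seed))
write_eeg_dataset(mini, file.path(out_dir, "sample_dataset.json"),
                  montage = make_montage(8))

# ground-truth band amplitudes of the miniature design, for inspection
gt <- band_amplitude_ground_truth(mini$world, "gamma")
write.csv(gt, file.path(out_dir, "sample_gamma_amplitudes.csv"),
          row.names = FALSE)
cat("Wrote", out_dir, "\n")
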