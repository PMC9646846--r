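#!/usr/bin/env Rscript

# Stage 2: hand-crafted EEG encodings as classification baselines.
#
# Compares the three hand-crafted encodings (FFT band magnitudes,
# differential entropy, Morlet wavelet band power) per frequency band with
# a linear SVM, on a reduced design so the sweep stays desk-sized. The
# expected pattern mirrors the full study: DE is the strongest encoding,
# and its high-frequency bands carry most of the class signal.

library(eegconsensus)

seed <- 1
out_dir <- "results/02_feature_baselines"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(n_subjects = 10, n_channels = 16,
                        n_stimuli_per_class = 8, seed = seed)
world <- generate_world(cfg)
trials <- trial_table(world)
split <- make_split(world$stimuli, seed = seed)
member <- induced_split(split, trials$stimulus_id)
bands <- band_table("handcrafted")

encode <- function(encoder) {
  feats <- NULL
  for (i in seq_len(nrow(trials))) {
    ep <- generate_epoch(world, trials$subject_id[i], trials$stimulus_id[i])
    v <- encoder(ep)
    if (is.null(feats)) feats <- matrix(NA_real_, nrow(trials), length(v))
    feats[i, ] <- v
  }
  feats
}

svm_accuracy <- function(feats) {
  sc <- fit_scaler(feats[member == "train", , drop = FALSE])
  spec <- classifier_spec("linear_svm", n_classes = cfg$n_classes)
  m <- train_classifier(spec,
                        apply_scaler(sc, feats[member == "train", , drop = FALSE]),
                        trials$class_label[member == "train"])
  mean(predict(m, apply_scaler(sc, feats[member == "test", , drop = FALSE])) ==
         trials$class_label[member == "test"])
}

rows <- list()
for (b in names(bands)) {
  cat("band", b, "... ")
  acc_fft <- svm_accuracy(encode(function(ep)
    fft_features(extract_analysis_window(normalize_channels(ep)), bands[[b]])))
  acc_de <- svm_accuracy(encode(function(ep)
    de_features(extract_analysis_window(normalize_channels(ep)), bands[[b]])))
  acc_wav <- svm_accuracy(encode(function(ep)
    wavelet_features(normalize_channels(ep), bands = bands[b])))
  rows[[b]] <- data.frame(band = b, fft = acc_fft, de = acc_de,
                          wavelet = acc_wav)
  cat(sprintf("FFT %.3f  DE %.3f  wavelet %.3f\n",
              acc_fft, acc_de, acc_wav))
}
tbl <- do.call(rbind, rows)
write.csv(tbl, file.path(out_dir, "handcrafted_baselines.csv"),
          row.names = FALSE)
cat("Best cell:", tbl$band[which.max(apply(tbl[, -1], 1, max))],
    "/", names(tbl[, -1])[which.max(apply(tbl[, -1], 2, max))], "\n")
cat("Wrote", out_dir, "\n")
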