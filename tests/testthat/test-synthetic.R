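test_that("config validation rejects degenerate designs", {
  expect_error(small_config(n_subjects = 0), "n_subjects")
  expect_error(small_config(eeg_noise_scale = -1), "eeg_noise_scale")
  expect_error(small_config(classes_per_subject = 3), "two-half")
  expect_error(generator_config(n_classes = 4, classes_per_subject = 5,
                                n_subjects = 4),
               "exceeds")
})

test_that("generator is bit-identical under identical seed and config", {
  cfg <- tiny_config(seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$epochs, d2$epochs)
  expect_identical(d1$video_features, d2$video_features)
  d3 <- generate_dataset(tiny_config(seed = 8))
  expect_false(identical(d1$epochs[[1]]$signal, d3$epochs[[1]]$signal))
})

test_that("without subject effects or noise all subjects record the same signal", {
  cfg <- tiny_config(subject_bias_scale = 0, eeg_noise_scale = 0)
  w <- generate_world(cfg)
  stim <- w$stimuli$stimulus_id[1]
  watchers <- trial_table(w)
  watchers <- watchers$subject_id[watchers$stimulus_id == stim]
  expect_gt(length(watchers), 1)
  sigs <- lapply(watchers, function(s) generate_epoch(w, s, stim)$signal)
  for (i in seq_along(sigs)[-1]) expect_equal(sigs[[i]], sigs[[1]])
})

test_that("each stimulus is watched by exactly half the subjects", {
  w <- generate_world(generator_config(seed = 1))   # default design
  tt <- trial_table(w)
  per_stim <- table(tt$stimulus_id)
  expect_true(all(per_stim == 25))
  expect_identical(anyDuplicated(paste(tt$subject_id, tt$stimulus_id)), 0L)
  # every subject sees one epoch per stimulus of each assigned class
  per_subj <- table(tt$subject_id)
  expect_true(all(per_subj == 5 * 24))
})

test_that("epoch geometry matches the configuration", {
  cfg <- tiny_config()
  w <- generate_world(cfg)
  tt <- trial_table(w)
  ep <- generate_epoch(w, tt$subject_id[1], tt$stimulus_id[1])
  expect_equal(dim(ep$signal),
               c(cfg$n_channels, cfg$pre_stimulus_samples + cfg$n_samples))
  expect_true(all(is.finite(ep$signal)))
  # pre-stimulus segment is noise only: with zero noise it is exactly zero
  w0 <- generate_world(tiny_config(eeg_noise_scale = 0))
  ep0 <- generate_epoch(w0, tt$subject_id[1], tt$stimulus_id[1])
  expect_true(all(ep0$signal[, 1:cfg$pre_stimulus_samples] == 0))
})

test_that("ground-truth amplitude table covers every trial-channel triple", {
  cfg <- tiny_config(eeg_noise_scale = 0)
  w <- generate_world(cfg)
  gt <- band_amplitude_ground_truth(w, "gamma")
  tt <- trial_table(w)
  expect_equal(nrow(gt), nrow(tt) * cfg$n_channels)
  expect_true(all(gt$amplitude >= cfg$amplitude_floor))
  expect_error(band_amplitude_ground_truth(w, "delta"), "unknown band")
})

test_that("noise-free band power equals amplitude^2 * N / 2 and DE tracks it", {
  cfg <- tiny_config(eeg_noise_scale = 0)
  w <- generate_world(cfg)
  tt <- trial_table(w)
  gt <- band_amplitude_ground_truth(w, "gamma")
  band <- band_table("handcrafted")$gamma
  for (i in c(1, 5)) {
    ep <- extract_analysis_window(
      generate_epoch(w, tt$subject_id[i], tt$stimulus_id[i]))
    h <- de_features(ep, band)
    amps <- gt$amplitude[gt$subject_id == tt$subject_id[i] &
                         gt$stimulus_id == tt$stimulus_id[i]]
    # carriers sit on DFT bins, so band power is exactly A^2 * N / 2
    expect_equal(exp(2 * (h - 0.5 * log(2 * pi * exp(1) / 750))),
                 (amps^2 * 750 / 2)^1, tolerance = 1e-8)
    # monotone recovery where amplitudes are distinct (floor clipping can
    # produce exact ties whose DE values differ only in the last ulp)
    keep <- amps > cfg$amplitude_floor
    expect_gt(sum(keep), 2)
    expect_equal(stats::cor(h[keep], log(amps[keep]), method = "spearman"), 1)
  }
})

test_that("subject-averaged trial latents concentrate as 1/sqrt(n)", {
  cfg <- generator_config(n_classes = 2, classes_per_subject = 1,
                          n_subjects = 40, n_stimuli_per_class = 2,
                          n_channels = 8, seed = 3)
  w <- generate_world(cfg)
  tt <- trial_table(w)
  stim <- tt$stimulus_id[1]
  watchers <- tt$subject_id[tt$stimulus_id == stim]
  j <- match(stim, w$stimuli$stimulus_id)
  lat <- t(vapply(watchers, function(s)
    eegconsensus:::trial_latent(w, match(s, w$subjects$subject_id), j),
    numeric(cfg$latent_dim)))
  # mean bias is ~identity, so averaged latents approach the stimulus latent
  target <- w$latents[, j]
  err_at <- function(n) {
    reps <- vapply(1:30, function(r) {
      idx <- sample(nrow(lat), n)
      sqrt(sum((colMeans(lat[idx, , drop = FALSE]) - target)^2))
    }, numeric(1))
    mean(reps)
  }
  set.seed(11)
  e1 <- err_at(1); e4 <- err_at(4); e16 <- err_at(16)
  expect_gt(e1, e4)
  expect_gt(e4, e16)
  # shrinkage roughly follows 1/sqrt(n): quartering n doubles the error
  expect_gt(e1 / e4, 1.5)
  expect_gt(e4 / e16, 1.5)
})

test_that("EEG features separate classes better than the noisier video view", {
  # premise of the whole analysis, checked by a stimulus-level linear probe;
  # moderate subject bias isolates the video_noise > eeg_noise mechanism
  accs <- vapply(1:3, function(seed) {
    cfg <- small_config(seed = seed, subject_bias_scale = 0.5)
    w <- generate_world(cfg)
    de <- dataset_de_features(w)
    labels <- stats::setNames(w$stimuli$class_label, w$stimuli$stimulus_id)
    stim_feats <- rowsum(de$features, de$meta$stimulus_id)
    stim_feats <- stim_feats / as.numeric(table(de$meta$stimulus_id))
    vf <- w$video_features
    rownames(vf) <- w$stimuli$stimulus_id
    split <- make_split(w$stimuli, seed = seed)
    probe <- function(x) {
      sc <- fit_scaler(x[split$train_stimuli, , drop = FALSE])
      spec <- classifier_spec("linear_student", n_classes = cfg$n_classes,
                              epochs = 150, seed = seed)
      m <- train_classifier(spec,
                            apply_scaler(sc, x[split$train_stimuli, , drop = FALSE]),
                            labels[split$train_stimuli])
      mean(predict(m, apply_scaler(sc, x[split$test_stimuli, , drop = FALSE])) ==
             labels[split$test_stimuli])
    }
    c(eeg = probe(stim_feats), video = probe(vf))
  }, numeric(2))
  expect_gt(mean(accs["eeg", ]), mean(accs["video", ]))
})
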