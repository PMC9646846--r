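#' Configuration for the synthetic multi-subject EEG experiment
#'
#' The generator emulates a block-design acquisition in which every subject
#' watches all stimuli of half of the action classes, one trial per stimulus:
#' each class has a latent concept vector, each stimulus is a noisy copy of
#' its class concept, each subject views the world through a fixed linear
#' bias transform, and each trial adds latent and sensor noise. Channel
#' signals are sums of band-limited oscillations (one carrier per canonical
#' band) whose per-channel amplitudes are a fixed linear readout of the
#' trial latent; the video modality is a different (noisier, by default)
#' linear readout of the same stimulus latent.
#'
#' @param n_classes number of action classes.
#' @param n_stimuli_per_class stimuli (video clips) per class.
#' @param n_subjects number of subjects; split into two halves, each half
#'   assigned a disjoint set of `classes_per_subject` classes.
#' @param classes_per_subject classes watched by each subject; the two-half
#'   design requires `2 * classes_per_subject == n_classes`.
#' @param n_channels EEG channels.
#' @param n_samples stimulus-on samples per trial (750 = 3 s at 250 Hz).
#' @param pre_stimulus_samples baseline samples before stimulus onset
#'   (250 = 1 s of inter-stimulus interval, kept for wavelet baselining).
#' @param sampling_rate Hz.
#' @param subject_bias_scale size of the subject-specific perturbation of
#'   the identity bias transform (0 = no subject effect).
#' @param eeg_noise_scale standard deviation of the white sensor noise, in
#'   the same units as the unit-order carrier amplitudes; also scales the
#'   per-trial latent jitter (at half this value).
#' @param video_noise_scale standard deviation of the additive noise on the
#'   video feature readout.
#' @param stimulus_noise_scale spread of stimuli around their class concept.
#' @param latent_dim dimension of the concept space.
#' @param video_dim length of the per-stimulus video feature vector.
#' @param carrier_freqs named numeric vector, one carrier frequency (Hz) per
#'   band of the hand-crafted band table.
#' @param base_amplitude,readout_scale,amplitude_floor mean, spread and lower
#'   clip of the per-channel per-band carrier amplitudes.
#' @param seed integer master seed; every random draw in the generator is
#'   derived from it through a fixed stream-splitting scheme, so identical
#'   configurations reproduce bit-identical datasets.
#' @return A `generator_config` list.
#' @examples
#' cfg <- generator_config(n_subjects = 4, n_classes = 2,
#'                         classes_per_subject = 1, n_stimuli_per_class = 3,
#'                         n_channels = 8, seed = 1)
#' @export
generator_config <- function(n_classes = 10,
                             n_stimuli_per_class = 24,
                             n_subjects = 50,
                             classes_per_subject = 5,
                             n_channels = 62,
                             n_samples = 750,
                             pre_stimulus_samples = 250,
                             sampling_rate = 250,
                             subject_bias_scale = 2.0,
                             eeg_noise_scale = 0.3,
                             video_noise_scale = 4.0,
                             stimulus_noise_scale = 1.8,
                             latent_dim = 12,
                             video_dim = 50,
                             carrier_freqs = c(theta = 6, alpha = 10,
                                               beta = 22, gamma = 45),
                             base_amplitude = 1.0,
                             readout_scale = 0.45,
                             amplitude_floor = 0.05,
                             seed = 1L) {
  cfg <- list(
    n_classes = as.integer(n_classes),
    n_stimuli_per_class = as.integer(n_stimuli_per_class),
    n_subjects = as.integer(n_subjects),
    classes_per_subject = as.integer(classes_per_subject),
    n_channels = as.integer(n_channels),
    n_samples = as.integer(n_samples),
    pre_stimulus_samples = as.integer(pre_stimulus_samples),
    sampling_rate = sampling_rate,
    subject_bias_scale = subject_bias_scale,
    eeg_noise_scale = eeg_noise_scale,
    video_noise_scale = video_noise_scale,
    stimulus_noise_scale = stimulus_noise_scale,
    latent_dim = as.integer(latent_dim),
    video_dim = as.integer(video_dim),
    carrier_freqs = carrier_freqs,
    base_amplitude = base_amplitude,
    readout_scale = readout_scale,
    amplitude_floor = amplitude_floor,
    seed = as.integer(seed)
  )
  counts <- c("n_classes", "n_stimuli_per_class", "n_subjects",
              "classes_per_subject", "n_channels", "n_samples",
              "latent_dim", "video_dim")
  for (nm in counts) {
    if (cfg[[nm]] < 1L) stopf("%s must be >= 1 (got %d)", nm, cfg[[nm]])
  }
  if (cfg$pre_stimulus_samples < 0L) stopf("pre_stimulus_samples must be >= 0")
  for (nm in c("subject_bias_scale", "eeg_noise_scale", "video_noise_scale",
               "stimulus_noise_scale")) {
    if (cfg[[nm]] < 0) stopf("%s must be >= 0", nm)
  }
  if (cfg$classes_per_subject > cfg$n_classes) {
    stopf("classes_per_subject (%d) exceeds n_classes (%d)",
          cfg$classes_per_subject, cfg$n_classes)
  }
  if (2L * cfg$classes_per_subject != cfg$n_classes) {
    stopf(paste("the two-half class assignment requires",
                "2 * classes_per_subject == n_classes (got %d and %d)"),
          cfg$classes_per_subject, cfg$n_classes)
  }
  if (any(carrier_freqs >= sampling_rate / 2)) {
    stopf("carrier frequencies must be below Nyquist (%g Hz)",
          sampling_rate / 2)
  }
  class(cfg) <- "generator_config"
  cfg
}

#' One EEG trial
#'
#' @param signal channels x samples numeric matrix (pre-stimulus segment
#'   first, then the stimulus-on window).
#' @param subject_id,stimulus_id identifiers; the pair is unique in a dataset.
#' @param class_label integer class in `[0, n_classes)`.
#' @param sampling_rate Hz.
#' @param pre_stimulus_samples leading baseline samples contained in `signal`.
#' @return An `eeg_epoch` object.
#' @export
eeg_epoch <- function(signal, subject_id, stimulus_id, class_label,
                      sampling_rate, pre_stimulus_samples = 0L) {
  stopifnot(is.matrix(signal))
  if (!all(is.finite(signal))) stopf("epoch signal contains non-finite values")
  structure(
    list(signal = signal,
         subject_id = subject_id,
         stimulus_id = stimulus_id,
         class_label = as.integer(class_label),
         sampling_rate = sampling_rate,
         pre_stimulus_samples = as.integer(pre_stimulus_samples)),
    class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch %s/%s class %d: %d ch x %d samples (%d pre) @ %g Hz>\n",
              x$subject_id, x$stimulus_id, x$class_label,
              nrow(x$signal), ncol(x$signal), x$pre_stimulus_samples,
              x$sampling_rate))
  invisible(x)
}

## ---- latent world -------------------------------------------------------

## Stream keys for seed derivation (fixed; part of the generator contract).
.STREAM <- list(concepts = 1L, stimulus = 2L, phases = 3L, bias = 4L,
                trial = 5L, sensor = 6L, video = 7L, assignment = 8L,
                readout = 9L)

#' Draw the latent structure of a synthetic experiment
#'
#' Materialises everything except the per-trial signals: class concepts,
#' stimulus latents and video features, subject bias transforms and class
#' assignments, and the fixed amplitude readout. Epoch signals are then
#' produced on demand by [generate_epoch()], so large designs never need all
#' trials in memory at once.
#'
#' @param config a [generator_config()].
#' @return A `generator_world` list with elements `config`, `stimuli`
#'   (tibble: stimulus_id, class_label, plus latent/video matrices),
#'   `subjects` (tibble: subject_id, half), `assignment` (subject x class
#'   logical matrix), `concepts`, `bias` (array), `readout` (per-band list).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  d <- config$latent_dim
  K <- config$n_classes
  J <- K * config$n_stimuli_per_class
  S <- config$n_subjects
  nch <- config$n_channels
  bands <- names(config$carrier_freqs)

  concepts <- with_seed(derive_seed(config$seed, .STREAM$concepts),
                        matrix(stats::rnorm(d * K), nrow = d))

  class_of <- rep(seq_len(K) - 1L, each = config$n_stimuli_per_class)
  stim_ids <- sprintf("V%03d", seq_len(J))
  latents <- matrix(0, nrow = d, ncol = J)
  phases <- array(0, dim = c(nch, length(bands), J),
                  dimnames = list(NULL, bands, stim_ids))
  for (j in seq_len(J)) {
    latents[, j] <- concepts[, class_of[j] + 1L] +
      with_seed(derive_seed(config$seed, .STREAM$stimulus, j),
                stats::rnorm(d, sd = config$stimulus_noise_scale))
    phases[, , j] <- with_seed(derive_seed(config$seed, .STREAM$phases, j),
                               matrix(stats::runif(nch * length(bands),
                                                   0, 2 * pi),
                                      nrow = nch))
  }

  video_map <- with_seed(derive_seed(config$seed, .STREAM$readout, 0L),
                         matrix(stats::rnorm(config$video_dim * d, sd = 1 / sqrt(d)),
                                nrow = config$video_dim))
  video_feats <- matrix(0, nrow = J, ncol = config$video_dim)
  for (j in seq_len(J)) {
    video_feats[j, ] <- as.numeric(video_map %*% latents[, j]) +
      with_seed(derive_seed(config$seed, .STREAM$video, j),
                stats::rnorm(config$video_dim, sd = config$video_noise_scale))
  }

  ## per-band fixed linear readout of the latent into channel amplitudes
  readout <- lapply(seq_along(bands), function(b) {
    with_seed(derive_seed(config$seed, .STREAM$readout, b),
              matrix(stats::rnorm(nch * d, sd = config$readout_scale / sqrt(d)),
                     nrow = nch))
  })
  names(readout) <- bands

  ## subject bias transforms: identity + scale * random perturbation
  bias <- array(0, dim = c(d, d, S))
  for (s in seq_len(S)) {
    R <- with_seed(derive_seed(config$seed, .STREAM$bias, s),
                   matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), nrow = d))
    bias[, , s] <- diag(d) + config$subject_bias_scale * R
  }

  ## two-half class assignment
  half_a_classes <- with_seed(derive_seed(config$seed, .STREAM$assignment),
                              sort(sample(seq_len(K) - 1L,
                                          config$classes_per_subject)))
  half_b_classes <- setdiff(seq_len(K) - 1L, half_a_classes)
  half <- rep(c("A", "B"), length.out = S)
  assignment <- matrix(FALSE, nrow = S, ncol = K,
                       dimnames = list(sprintf("S%02d", seq_len(S)),
                                       as.character(seq_len(K) - 1L)))
  for (s in seq_len(S)) {
    cls <- if (half[s] == "A") half_a_classes else half_b_classes
    assignment[s, cls + 1L] <- TRUE
  }

  structure(list(
    config = config,
    concepts = concepts,
    stimuli = tibble::tibble(stimulus_id = stim_ids, class_label = class_of),
    latents = latents,
    phases = phases,
    video_features = video_feats,
    readout = readout,
    bias = bias,
    subjects = tibble::tibble(subject_id = sprintf("S%02d", seq_len(S)),
                              half = half),
    assignment = assignment
  ), class = "generator_world")
}

subject_index <- function(world, subject_id) {
  i <- match(subject_id, world$subjects$subject_id)
  if (is.na(i)) stopf("unknown subject '%s'", subject_id)
  i
}

stimulus_index <- function(world, stimulus_id) {
  j <- match(stimulus_id, world$stimuli$stimulus_id)
  if (is.na(j)) stopf("unknown stimulus '%s'", stimulus_id)
  j
}

## Trial latent for (subject, stimulus): bias-transformed stimulus latent
## plus per-trial jitter (scaled by half the sensor-noise scale).
trial_latent <- function(world, s, j) {
  cfg <- world$config
  u <- as.numeric(world$bias[, , s] %*% world$latents[, j])
  if (cfg$eeg_noise_scale > 0) {
    u <- u + with_seed(derive_seed(cfg$seed, .STREAM$trial, s, j),
                       stats::rnorm(cfg$latent_dim,
                                    sd = 0.5 * cfg$eeg_noise_scale))
  }
  u
}

## Per-channel, per-band carrier amplitudes for one trial (channels x bands).
trial_amplitudes <- function(world, s, j) {
  cfg <- world$config
  u <- trial_latent(world, s, j)
  amps <- vapply(world$readout,
                 function(W) pmax(cfg$base_amplitude + as.numeric(W %*% u),
                                  cfg$amplitude_floor),
                 numeric(cfg$n_channels))
  amps
}

#' Synthesise one epoch of a generated experiment
#'
#' @param world a [generate_world()] result.
#' @param subject_id,stimulus_id identifiers present in the world.
#' @return An [eeg_epoch()]; the pre-stimulus segment carries sensor noise
#'   only, the stimulus window adds the band-limited carriers.
#' @export
generate_epoch <- function(world, subject_id, stimulus_id) {
  cfg <- world$config
  s <- subject_index(world, subject_id)
  j <- stimulus_index(world, stimulus_id)
  amps <- trial_amplitudes(world, s, j)          # channels x bands
  phi <- world$phases[, , j, drop = FALSE]
  dim(phi) <- dim(phi)[1:2]

  tt <- (seq_len(cfg$n_samples) - 1L) / cfg$sampling_rate
  stim <- matrix(0, nrow = cfg$n_channels, ncol = cfg$n_samples)
  for (b in seq_along(cfg$carrier_freqs)) {
    w <- 2 * pi * cfg$carrier_freqs[b]
    ## A * sin(w t + phi) = (A cos phi) sin(w t) + (A sin phi) cos(w t)
    stim <- stim + outer(amps[, b] * cos(phi[, b]), sin(w * tt)) +
      outer(amps[, b] * sin(phi[, b]), cos(w * tt))
  }
  total <- cfg$pre_stimulus_samples + cfg$n_samples
  signal <- cbind(matrix(0, cfg$n_channels, cfg$pre_stimulus_samples), stim)
  if (cfg$eeg_noise_scale > 0) {
    signal <- signal +
      with_seed(derive_seed(cfg$seed, .STREAM$sensor, s, j),
                matrix(stats::rnorm(cfg$n_channels * total,
                                    sd = cfg$eeg_noise_scale),
                       nrow = cfg$n_channels))
  }
  eeg_epoch(signal, subject_id, world$stimuli$stimulus_id[j],
            world$stimuli$class_label[j], cfg$sampling_rate,
            cfg$pre_stimulus_samples)
}

#' Enumerate the (subject, stimulus) trials of a design
#'
#' @param world a generator world.
#' @return Tibble with subject_id, stimulus_id, class_label, one row per
#'   trial a subject actually watched (only their assigned classes).
#' @export
trial_table <- function(world) {
  rows <- list()
  for (s in seq_len(nrow(world$subjects))) {
    cls <- which(world$assignment[s, ]) - 1L
    keep <- world$stimuli$class_label %in% cls
    rows[[s]] <- tibble::tibble(
      subject_id = world$subjects$subject_id[s],
      stimulus_id = world$stimuli$stimulus_id[keep],
      class_label = world$stimuli$class_label[keep])
  }
  do.call(rbind, rows)
}

#' Generate a full synthetic dataset
#'
#' Materialises every epoch of the design. Memory grows as
#' subjects x stimuli x channels x samples; for large designs prefer
#' [generate_world()] + [generate_epoch()] or the streaming feature
#' extractor [dataset_de_features()].
#'
#' @param config a [generator_config()].
#' @return List with `epochs` (list of [eeg_epoch()]), `stimuli` (tibble with
#'   class labels and video feature matrix in `$video_features`), `subjects`,
#'   `trials` and the underlying `world`.
#' @export
generate_dataset <- function(config) {
  world <- generate_world(config)
  trials <- trial_table(world)
  epochs <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    epochs[[i]] <- generate_epoch(world, trials$subject_id[i],
                                  trials$stimulus_id[i])
  }
  list(epochs = epochs,
       stimuli = world$stimuli,
       video_features = world$video_features,
       subjects = world$subjects,
       trials = trials,
       world = world)
}

#' Ground-truth injected band amplitudes
#'
#' Returns the exact per-channel carrier amplitude the generator injected for
#' every trial, for use as an oracle when validating feature extraction:
#' with no sensor noise, band power in the carrier's band is exactly
#' amplitude^2 * n_samples / 2.
#'
#' @param world a generator world (or the `world` element of
#'   [generate_dataset()] output).
#' @param band band label; must be one of the generator's carrier bands.
#' @return Tibble with columns stimulus_id, subject_id, channel, amplitude —
#'   one row per (stimulus, subject, channel) triple of the design.
#' @export
band_amplitude_ground_truth <- function(world, band) {
  if (!is.null(world$world)) world <- world$world
  stopifnot(inherits(world, "generator_world"))
  bands <- names(world$config$carrier_freqs)
  if (!band %in% bands) {
    stopf("unknown band '%s'; generator bands are: %s",
          band, paste(bands, collapse = ", "))
  }
  b <- match(band, bands)
  trials <- trial_table(world)
  nch <- world$config$n_channels
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    s <- subject_index(world, trials$subject_id[i])
    j <- stimulus_index(world, trials$stimulus_id[i])
    amps <- trial_amplitudes(world, s, j)
    out[[i]] <- tibble::tibble(stimulus_id = trials$stimulus_id[i],
                               subject_id = trials$subject_id[i],
                               channel = seq_len(nch),
                               amplitude = amps[, b])
  }
  do.call(rbind, out)
}

#' Stream differential-entropy features over a whole design
#'
#' Generates each epoch, applies the configured conditioning (channel
#' normalisation, analysis-window extraction) and computes per-channel DE in
#' each band, discarding the raw signal immediately — the memory footprint is
#' one epoch, not the dataset.
#'
#' @param world a generator world or a [generator_config()].
#' @param bands list of [band_definition()]s (default: hand-crafted table).
#' @param normalize apply per-channel \[-1, 1\] normalisation first (default
#'   TRUE, the conventional conditioning for this encoding).
#' @return List: `features` (trials x (channels * bands) matrix, column
#'   order channel-major within band), `meta` (tibble subject_id,
#'   stimulus_id, class_label).
#' @export
dataset_de_features <- function(world, bands = band_table("handcrafted"),
                                normalize = TRUE) {
  if (inherits(world, "generator_config")) world <- generate_world(world)
  trials <- trial_table(world)
  nch <- world$config$n_channels
  feats <- matrix(NA_real_, nrow = nrow(trials),
                  ncol = nch * length(bands))
  colnames(feats) <- as.vector(vapply(
    names(bands), function(b) sprintf("de_%s_ch%02d", b, seq_len(nch)),
    character(nch)))
  for (i in seq_len(nrow(trials))) {
    ep <- generate_epoch(world, trials$subject_id[i], trials$stimulus_id[i])
    if (normalize) ep <- normalize_channels(ep)
    win <- extract_analysis_window(ep)
    feats[i, ] <- as.vector(de_feature_matrix(win$signal, bands,
                                              world$config$sampling_rate))
  }
  list(features = feats, meta = trials)
}
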