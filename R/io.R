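#' Write a generated dataset to a structured container file
#'
#' Serialises a [generate_dataset()] result — epochs (channels x samples
#' matrices with metadata), the stimulus table with video features, and the
#' subject table — into a single JSON container, with full numeric
#' precision. A plain CSV montage file is written alongside when a layout is
#' supplied. Intended for desk-scale datasets; large designs are better
#' regenerated from their [generator_config()].
#'
#' @param dataset a [generate_dataset()] result.
#' @param path output `.json` path.
#' @param montage optional `montage_layout`; written as `<path>_montage.csv`.
#' @return Invisibly, `path`.
#' @export
write_eeg_dataset <- function(dataset, path, montage = NULL) {
  payload <- list(
    format = "eegconsensus-dataset",
    version = 1L,
    config = unclass(dataset$world$config),
    stimuli = dataset$stimuli,
    video_features = dataset$video_features,
    subjects = dataset$subjects,
    epochs = lapply(dataset$epochs, function(ep) {
      list(subject_id = ep$subject_id,
           stimulus_id = ep$stimulus_id,
           class_label = ep$class_label,
           sampling_rate = ep$sampling_rate,
           pre_stimulus_samples = ep$pre_stimulus_samples,
           signal = ep$signal)
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  if (!is.null(montage)) {
    write_montage_csv(montage, sub("\\.json$", "_montage.csv", path))
  }
  invisible(path)
}

#' @rdname write_eeg_dataset
#' @return `read_eeg_dataset` returns a list with `epochs`, `stimuli`,
#'   `video_features`, `subjects` and `config` (the world itself is not
#'   stored; regenerate it from the config when latent ground truth is
#'   needed).
#' @export
read_eeg_dataset <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "eegconsensus-dataset")) {
    stopf("'%s' is not an eegconsensus dataset container", path)
  }
  as_matrix <- function(rows) do.call(rbind, lapply(rows, unlist))
  epochs <- lapply(payload$epochs, function(ep) {
    eeg_epoch(as_matrix(ep$signal), ep$subject_id, ep$stimulus_id,
              ep$class_label, ep$sampling_rate, ep$pre_stimulus_samples)
  })
  cfg <- payload$config
  cfg$carrier_freqs <- unlist(cfg$carrier_freqs)
  config <- do.call(generator_config, cfg)
  stimuli <- tibble::tibble(
    stimulus_id = vapply(payload$stimuli, function(r) r$stimulus_id, ""),
    class_label = vapply(payload$stimuli, function(r)
      as.integer(r$class_label), integer(1)))
  subjects <- tibble::tibble(
    subject_id = vapply(payload$subjects, function(r) r$subject_id, ""),
    half = vapply(payload$subjects, function(r) r$half, ""))
  list(epochs = epochs,
       stimuli = stimuli,
       video_features = as_matrix(payload$video_features),
       subjects = subjects,
       config = config)
}
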