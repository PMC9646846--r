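#' Run the full subjects'-consensus analysis pipeline
#'
#' Orchestrates the whole study on one synthetic experiment: generate the
#' latent world, stream per-epoch differential-entropy features, make the
#' stratified stimulus split (EEG split induced), train one DE+MLP per
#' subject, form subjects'-consensus predictions on the test stimuli,
#' compute the accuracy-versus-subjects curve and the per-class ROC/AUC with
#' and without consensus, train the video-only student, optionally sweep the
#' distillation grid, and evaluate the two fusion baselines. Every stage
#' draws its randomness from the configuration seed, so the report is a
#' deterministic function of the configuration.
#'
#' @param config a [generator_config()].
#' @param proportions split proportions (rescaled to the stimulus count).
#' @param n_grid subject-count grid for the consensus curve.
#' @param resamples random subject subsets per curve point.
#' @param mlp_epochs,student_epochs training epoch budgets.
#' @param with_distillation run the (T, lambda) grid (slowest stage).
#' @param distill_temperatures,distill_lambdas,distill_runs grid settings.
#' @param curve compute the accuracy-versus-subjects curve.
#' @return A `consensus_report` list; see Details.
#' @details The returned list contains: `config`, `split`, `records`
#'   (test-epoch logits), `consensus` (test consensus table),
#'   `accuracy` (tibble of the headline accuracies),
#'   `curve` (accuracy vs number of subjects), `roc_single`, `roc_consensus`
#'   (per-class AUC tables), `video` (student baseline), `distillation`
#'   (grid results or NULL), `fusion` (kernel and logit fusion accuracies),
#'   and `summary` — the four-column overview (EEG only, video only,
#'   consensus-distilled video, fusion).
#' @export
run_pipeline <- function(config,
                         proportions = c(140, 40, 60),
                         n_grid = c(1, 2, 5, 10, 15, 20, 25),
                         resamples = 20,
                         mlp_epochs = 60,
                         student_epochs = 200,
                         with_distillation = TRUE,
                         distill_temperatures = c(1, 2, 5, 10, 20, 50),
                         distill_lambdas = c(0.25, 0.5, 0.75, 1),
                         distill_runs = 5,
                         curve = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  world <- generate_world(config)
  labels <- stats::setNames(world$stimuli$class_label,
                            world$stimuli$stimulus_id)

  de <- dataset_de_features(world)
  split <- make_split(world$stimuli, proportions, seed = config$seed)
  member <- induced_split(split, de$meta$stimulus_id)

  scaler <- fit_scaler(de$features[member == "train", , drop = FALSE])
  feats <- apply_scaler(scaler, de$features)

  ## one DE+MLP per subject, trained on that subject's training epochs
  subjects <- world$subjects$subject_id
  rec_rows <- list()
  single_acc <- numeric(0)
  for (s in subjects) {
    tr_idx <- which(de$meta$subject_id == s & member == "train")
    ev_idx <- which(de$meta$subject_id == s)    # teacher scores every split
    if (length(tr_idx) == 0) next
    spec <- classifier_spec("de_mlp", n_classes = config$n_classes,
                            epochs = mlp_epochs,
                            seed = derive_seed(config$seed, 10L, match(s, subjects)))
    mdl <- train_classifier(spec, feats[tr_idx, , drop = FALSE],
                            de$meta$class_label[tr_idx])
    z <- logits(mdl, feats[ev_idx, , drop = FALSE])
    rec_rows[[s]] <- logits_records(
      model_id = paste0("de_mlp_", s),
      subject_id = s,
      stimulus_id = de$meta$stimulus_id[ev_idx],
      logits_matrix = z,
      class_label = de$meta$class_label[ev_idx])
    te <- de$meta$stimulus_id[ev_idx] %in% split$test_stimuli
    if (any(te)) {
      pred <- apply(z[te, , drop = FALSE], 1, argmax1) - 1L
      single_acc <- c(single_acc,
                      mean(pred == de$meta$class_label[ev_idx][te]))
    }
  }
  records <- do.call(rbind, rec_rows)
  class(records) <- c("logits_records", class(tibble::tibble()))
  test_records <- records[records$stimulus_id %in% split$test_stimuli, ]

  cons <- consensus_table(test_records, labels)
  consensus_acc <- mean(cons$predicted == cons$labels)

  curve_tbl <- NULL
  if (curve) {
    curve_tbl <- accuracy_vs_n_subjects(test_records, labels,
                                        n_grid = n_grid,
                                        resamples = resamples,
                                        seed = derive_seed(config$seed, 20L))
  }

  ## per-class ROC: single-subject (pooled per-epoch scores) vs consensus
  single_probs <- softmax(test_records$logits)
  roc_single <- per_class_roc(single_probs, test_records$class_label)
  roc_consensus <- per_class_roc(cons$probabilities, cons$labels)

  ## video-only student
  vf <- world$video_features
  rownames(vf) <- world$stimuli$stimulus_id
  s_spec <- classifier_spec("linear_student", n_classes = config$n_classes,
                            epochs = student_epochs,
                            seed = derive_seed(config$seed, 30L))
  v_scaler <- fit_scaler(vf[split$train_stimuli, , drop = FALSE])
  v_train <- apply_scaler(v_scaler, vf[split$train_stimuli, , drop = FALSE])
  v_test <- apply_scaler(v_scaler, vf[split$test_stimuli, , drop = FALSE])
  v_model <- train_classifier(s_spec, v_train, labels[split$train_stimuli])
  video_acc <- mean(predict(v_model, v_test) == labels[split$test_stimuli])

  distill_res <- NULL
  distilled_acc <- NA_real_
  if (with_distillation) {
    trainval_records <- records[records$stimulus_id %in%
                                  c(split$train_stimuli, split$val_stimuli), ]
    distill_res <- run_grid(trainval_records, vf, labels, split,
                            temperatures = distill_temperatures,
                            lambdas = distill_lambdas,
                            n_runs = distill_runs,
                            spec = s_spec,
                            seed = derive_seed(config$seed, 40L))
    distilled_acc <- distill_res$best$test_mean
  }

  ## fusion: stimulus-level EEG block = subject-averaged DE features
  stim_feats <- rowsum(feats, de$meta$stimulus_id)
  stim_counts <- as.numeric(table(de$meta$stimulus_id)[rownames(stim_feats)])
  stim_feats <- stim_feats / stim_counts
  eeg_block_tr <- stim_feats[split$train_stimuli, , drop = FALSE]
  eeg_block_te <- stim_feats[split$test_stimuli, , drop = FALSE]
  kf <- kernel_fusion(list(eeg = eeg_block_tr,
                           video = vf[split$train_stimuli, , drop = FALSE]),
                      labels[split$train_stimuli])
  kf_pred <- predict(kf, list(eeg = eeg_block_te,
                              video = vf[split$test_stimuli, , drop = FALSE]))
  kernel_fusion_acc <- mean(kf_pred == labels[split$test_stimuli])

  cons_logits <- t(vapply(split$test_stimuli, function(stim)
    consensus_predict(test_records[test_records$stimulus_id == stim, ])$mean_logits,
    numeric(config$n_classes)))
  video_logits <- logits(v_model, v_test)
  lf <- logit_fusion(cons_logits, video_logits)
  logit_fusion_acc <- mean(lf$predicted == labels[split$test_stimuli])

  accuracy <- tibble::tibble(
    quantity = c("single_subject_mean", "consensus", "video_only",
                 "distilled_student", "kernel_fusion", "logit_fusion"),
    accuracy = c(mean(single_acc), consensus_acc, video_acc,
                 distilled_acc, kernel_fusion_acc, logit_fusion_acc))

  summary <- tibble::tibble(
    eeg_only = consensus_acc,
    video_only = video_acc,
    subjects_consensus = distilled_acc,
    fusion = max(kernel_fusion_acc, logit_fusion_acc))

  structure(list(config = config, split = split, records = records,
                 consensus = cons, accuracy = accuracy,
                 single_subject_accuracies = single_acc,
                 curve = curve_tbl,
                 roc_single = roc_single, roc_consensus = roc_consensus,
                 video_accuracy = video_acc,
                 distillation = distill_res,
                 fusion = tibble::tibble(kernel = kernel_fusion_acc,
                                         logit = logit_fusion_acc),
                 summary = summary),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report>\n")
  cat(sprintf("  %d classes, %d subjects, %d stimuli; seed %d\n",
              x$config$n_classes, x$config$n_subjects,
              x$config$n_stimuli_per_class * x$config$n_classes,
              x$config$seed))
  print(as.data.frame(x$accuracy), row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report as CSV files
#'
#' Emits the machine-readable pieces of a [run_pipeline()] report: headline
#' accuracies, consensus curve, per-class AUC tables, the distillation grid
#' and the four-column summary.
#'
#' @param report a `consensus_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_pipeline_report <- function(report, dir) {
  stopifnot(inherits(report, "consensus_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    files <<- c(files, path)
  }
  emit(report$accuracy, "accuracy.csv")
  if (!is.null(report$curve)) emit(report$curve, "consensus_curve.csv")
  emit(report$roc_single$per_class, "roc_single_subject.csv")
  emit(report$roc_consensus$per_class, "roc_consensus.csv")
  if (!is.null(report$distillation)) {
    emit(report$distillation$grid, "distillation_grid.csv")
  }
  emit(report$summary, "summary.csv")
  invisible(files)
}
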