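#' Stratified train / validation / test split of stimuli
#'
#' Randomly assigns stimuli to three disjoint splits in the given
#' proportions (140-40-60 for the canonical 240-stimulus design), stratified
#' by class so per-class counts deviate from exact proportionality by at
#' most one. The EEG split is induced: every epoch belongs to the split of
#' its stimulus, so no stimulus leaks across splits.
#'
#' @param stimuli tibble with columns `stimulus_id`, `class_label` (or a
#'   character vector of ids with `class_label` passed separately).
#' @param proportions three positive numbers; rescaled to the stimulus count.
#' @param seed integer seed.
#' @param class_label class per stimulus when `stimuli` is a plain vector.
#' @return A `dataset_split`: `train_stimuli`, `val_stimuli`,
#'   `test_stimuli` (character vectors), `seed`.
#' @export
make_split <- function(stimuli, proportions = c(140, 40, 60), seed = 1,
                       class_label = NULL) {
  if (is.data.frame(stimuli)) {
    ids <- stimuli$stimulus_id
    cls <- stimuli$class_label
  } else {
    ids <- as.character(stimuli)
    cls <- class_label
  }
  stopifnot(length(ids) == length(cls), length(proportions) == 3,
            all(proportions > 0))
  n <- length(ids)
  target <- proportions / sum(proportions) * n
  sizes <- floor(target)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_frac <- order(target - sizes, decreasing = TRUE)
    sizes[order_frac[seq_len(rem)]] <- sizes[order_frac[seq_len(rem)]] + 1
  }
  classes <- sort(unique(cls))
  parts <- list(character(0), character(0), character(0))
  ## largest-remainder apportionment per class, then a global fix-up pass
  per_class <- lapply(classes, function(k) {
    idk <- ids[cls == k]
    tk <- proportions / sum(proportions) * length(idk)
    sk <- floor(tk)
    rk <- length(idk) - sum(sk)
    if (rk > 0) {
      of <- order(tk - sk, decreasing = TRUE)
      sk[of[seq_len(rk)]] <- sk[of[seq_len(rk)]] + 1
    }
    list(ids = idk, sizes = sk)
  })
  ## reconcile per-class sizes with the global targets by moving single
  ## stimuli between the over- and under-full splits
  tot <- Reduce(`+`, lapply(per_class, `[[`, "sizes"))
  ki <- 1L
  while (any(tot != sizes)) {
    over <- which(tot > sizes)[1]
    under <- which(tot < sizes)[1]
    moved <- FALSE
    for (k in seq_along(per_class)) {
      ksz <- per_class[[k]]$sizes
      if (ksz[over] > 0) {
        per_class[[k]]$sizes[over] <- ksz[over] - 1
        per_class[[k]]$sizes[under] <- ksz[under] + 1
        moved <- TRUE
        break
      }
    }
    if (!moved) stopf("cannot reconcile split sizes")
    tot <- Reduce(`+`, lapply(per_class, `[[`, "sizes"))
    ki <- ki + 1L
    if (ki > 10L * length(ids)) stopf("split reconciliation did not converge")
  }
  for (k in seq_along(per_class)) {
    idk <- per_class[[k]]$ids
    sk <- per_class[[k]]$sizes
    if (any(sk > length(idk))) {
      stopf("class %s has too few stimuli (%d) for the split",
            classes[k], length(idk))
    }
    perm <- with_seed(derive_seed(seed, 50L, k), sample(idk))
    cuts <- cumsum(c(0, sk))
    for (p in 1:3) {
      parts[[p]] <- c(parts[[p]],
                      perm[seq_len(sk[p]) + cuts[p]])
    }
  }
  structure(list(train_stimuli = sort(parts[[1]]),
                 val_stimuli = sort(parts[[2]]),
                 test_stimuli = sort(parts[[3]]),
                 seed = seed),
            class = "dataset_split")
}

#' Split membership of epochs induced by the stimulus split
#'
#' @param split a `dataset_split`.
#' @param stimulus_ids stimulus of each epoch.
#' @return Character vector `"train"`, `"val"` or `"test"` per epoch.
#' @export
induced_split <- function(split, stimulus_ids) {
  out <- rep(NA_character_, length(stimulus_ids))
  out[stimulus_ids %in% split$train_stimuli] <- "train"
  out[stimulus_ids %in% split$val_stimuli] <- "val"
  out[stimulus_ids %in% split$test_stimuli] <- "test"
  if (anyNA(out)) stopf("epochs reference stimuli outside the split")
  out
}

#' Linear Gram matrix of a feature block
#'
#' @param x instances x features matrix.
#' @param y optional second matrix; returns the cross-Gram `x %*% t(y)`.
#' @return Instances x instances (or nrow(x) x nrow(y)) matrix.
#' @export
linear_gram <- function(x, y = NULL) {
  if (is.null(y)) tcrossprod(x) else tcrossprod(x, y)
}

#' Kernel (Gram-average) fusion classifier
#'
#' Standardises each feature block on the training instances, computes one
#' linear Gram matrix per block, averages the Grams, and trains a kernel
#' SVM on the fused (precomputed) kernel; prediction evaluates the fused
#' cross-kernel between new and training instances. Averaging linear Grams
#' is algebraically the linear kernel of the concatenated blocks scaled by
#' 1/2 (for two blocks), so the fused machine sees both modalities at equal
#' kernel weight.
#'
#' @param blocks named list of instances x features training matrices,
#'   aligned row-by-row.
#' @param y integer training labels in `[0, n_classes)`.
#' @param C SVM cost (libSVM-style default 1).
#' @return A `kernel_fusion_model`.
#' @export
kernel_fusion <- function(blocks, y, C = 1) {
  stopifnot(is.list(blocks), length(blocks) >= 2)
  n <- unique(vapply(blocks, nrow, integer(1)))
  if (length(n) != 1) stopf("feature blocks are misaligned across instances")
  scalers <- lapply(blocks, fit_scaler)
  xs <- Map(apply_scaler, scalers, blocks)
  K <- Reduce(`+`, lapply(xs, linear_gram)) / length(xs)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stopf("fused Gram is not positive semi-definite within tolerance")
  }
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K),
                       factor(y, levels = sort(unique(y))),
                       kernel = "matrix", C = C)
  structure(list(fit = fit, scalers = scalers, train_blocks = xs,
                 levels = sort(unique(y))),
            class = "kernel_fusion_model")
}

#' @rdname kernel_fusion
#' @param object a `kernel_fusion_model`.
#' @param newblocks named list of new feature blocks (same names/order and
#'   feature dimensions as at training).
#' @param ... unused.
#' @export
predict.kernel_fusion_model <- function(object, newblocks, ...) {
  stopifnot(length(newblocks) == length(object$train_blocks))
  xs <- Map(apply_scaler, object$scalers, newblocks)
  Kx <- Reduce(`+`, Map(linear_gram, xs, object$train_blocks)) /
    length(xs)
  ## ksvm keeps only the support vectors of the training Gram
  sv <- kernlab::SVindex(object$fit)
  pred <- kernlab::predict(object$fit,
                           kernlab::as.kernelMatrix(Kx[, sv, drop = FALSE]))
  as.integer(as.character(pred))
}

#' Late fusion of two models' logits
#'
#' Element-wise mean of two aligned logit matrices; the fused prediction is
#' the argmax (lowest class index on ties).
#'
#' @param logits_a,logits_b instances x n_classes matrices, aligned by row.
#' @return List: `logits` (fused matrix), `predicted` (integer labels).
#' @export
logit_fusion <- function(logits_a, logits_b) {
  if (!all(dim(logits_a) == dim(logits_b))) {
    stopf("logit matrices are misaligned: %s vs %s",
          paste(dim(logits_a), collapse = "x"),
          paste(dim(logits_b), collapse = "x"))
  }
  fused <- (logits_a + logits_b) / 2
  list(logits = fused, predicted = apply(fused, 1, argmax1) - 1L)
}

#' Complementary-modality fusion study
#'
#' Runs both fusion baselines on one generated experiment in the
#' complementary-noise condition: the video readout noise is set so the two
#' modalities have comparable single-modality quality while their noise
#' sources stay independent. The EEG modality enters at stimulus level as
#' the subject-averaged DE feature vector. Reports kernel-fusion and
#' logit-fusion test accuracy next to the single-modality references
#' (the same classifiers on each modality alone).
#'
#' @param seed generator seed.
#' @param config optional [generator_config()]; the default is a reduced
#'   design (20 subjects, 32 channels, 12 stimuli/class) with
#'   `video_noise_scale = 1` — the complementary-noise condition.
#' @param student_epochs training budget of the linear scorers.
#' @return Tibble with one row: kernel_eeg, kernel_video, kernel_fused,
#'   logit_eeg, logit_video, logit_fused (test accuracies).
#' @export
run_fusion_study <- function(seed, config = NULL, student_epochs = 150) {
  if (is.null(config)) {
    config <- generator_config(n_subjects = 20, n_channels = 32,
                               n_stimuli_per_class = 12,
                               video_noise_scale = 1.0, seed = seed)
  }
  w <- generate_world(config)
  de <- dataset_de_features(w)
  labels <- stats::setNames(w$stimuli$class_label, w$stimuli$stimulus_id)
  split <- make_split(w$stimuli, seed = seed)
  stim_feats <- rowsum(de$features, de$meta$stimulus_id)
  stim_feats <- stim_feats /
    as.numeric(table(de$meta$stimulus_id)[rownames(stim_feats)])
  vf <- w$video_features
  rownames(vf) <- w$stimuli$stimulus_id
  tr <- split$train_stimuli; te <- split$test_stimuli
  y_tr <- labels[tr]; y_te <- labels[te]

  kacc <- function(btr, bte) {
    m <- kernel_fusion(btr, y_tr)
    mean(predict(m, bte) == y_te)
  }
  e_tr <- stim_feats[tr, , drop = FALSE]; e_te <- stim_feats[te, , drop = FALSE]
  v_tr <- vf[tr, , drop = FALSE]; v_te <- vf[te, , drop = FALSE]
  kernel_eeg <- kacc(list(a = e_tr, b = e_tr), list(a = e_te, b = e_te))
  kernel_video <- kacc(list(a = v_tr, b = v_tr), list(a = v_te, b = v_te))
  kernel_fused <- kacc(list(eeg = e_tr, video = v_tr),
                       list(eeg = e_te, video = v_te))

  score <- function(x) {
    sc <- fit_scaler(x[tr, , drop = FALSE])
    sp <- classifier_spec("linear_student", n_classes = config$n_classes,
                          epochs = student_epochs, seed = seed)
    m <- train_classifier(sp, apply_scaler(sc, x[tr, , drop = FALSE]), y_tr)
    logits(m, apply_scaler(sc, x[te, , drop = FALSE]))
  }
  z_eeg <- score(stim_feats)
  z_vid <- score(vf)
  acc <- function(z) mean((apply(z, 1, argmax1) - 1L) == y_te)
  tibble::tibble(
    kernel_eeg = kernel_eeg, kernel_video = kernel_video,
    kernel_fused = kernel_fused,
    logit_eeg = acc(z_eeg), logit_video = acc(z_vid),
    logit_fused = mean(logit_fusion(z_eeg, z_vid)$predicted == y_te))
}
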