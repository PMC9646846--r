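#' Container for per-model class scores
#'
#' A thin tibble-based record set keyed by (model_id, subject_id,
#' stimulus_id) with the logit vectors as a matrix column, so downstream
#' consensus operations can slice by stimulus or subject without losing the
#' score geometry.
#'
#' @param model_id,subject_id,stimulus_id character vectors (recycled).
#' @param logits_matrix instances x n_classes numeric matrix.
#' @param class_label optional integer ground-truth labels.
#' @return A tibble of class `logits_records`.
#' @export
logits_records <- function(model_id, subject_id, stimulus_id, logits_matrix,
                           class_label = NULL) {
  stopifnot(is.matrix(logits_matrix), all(is.finite(logits_matrix)))
  out <- tibble::tibble(model_id = model_id, subject_id = subject_id,
                        stimulus_id = stimulus_id)
  if (!is.null(class_label)) out$class_label <- as.integer(class_label)
  out$logits <- logits_matrix
  class(out) <- c("logits_records", class(out))
  out
}

#' Subjects'-consensus prediction for one stimulus
#'
#' Averages the logit vectors that the chosen subjects' models produced for
#' one stimulus, then applies the softmax; the predicted class is the argmax
#' (lowest index on ties). Averaging probabilities instead of logits is
#' available for comparison.
#'
#' @param records a [logits_records()] tibble, all rows for one stimulus.
#' @param subset subjects to include (default: all subjects present).
#' @param average `"logits"` (default) or `"probabilities"`.
#' @return A `consensus_prediction`: stimulus_id, subject_ids_used,
#'   mean_logits, probabilities, predicted_class.
#' @export
consensus_predict <- function(records, subset = NULL,
                              average = c("logits", "probabilities")) {
  average <- match.arg(average)
  stims <- unique(records$stimulus_id)
  if (length(stims) != 1L) {
    stopf("records mix %d stimuli; consensus is per-stimulus", length(stims))
  }
  if (is.null(subset)) subset <- unique(records$subject_id)
  if (length(subset) == 0L) stopf("empty subject subset")
  missing <- setdiff(subset, records$subject_id)
  if (length(missing) > 0) {
    stopf("no records for subject(s): %s", paste(missing, collapse = ", "))
  }
  keep <- records$subject_id %in% subset
  Z <- records$logits[keep, , drop = FALSE]
  if (average == "logits") {
    mean_logits <- colMeans(Z)
    probs <- softmax(mean_logits)
  } else {
    probs <- colMeans(softmax(Z))
    mean_logits <- log(probs)        # representative logits for reporting
  }
  structure(list(stimulus_id = stims,
                 subject_ids_used = sort(unique(records$subject_id[keep])),
                 mean_logits = mean_logits,
                 probabilities = probs,
                 predicted_class = argmax1(if (average == "logits")
                   mean_logits else probs) - 1L),
            class = "consensus_prediction")
}

## Consensus probabilities for every stimulus in a record set; returns a
## list(prob matrix, predicted integer classes, stimulus ids, labels).
consensus_table <- function(records, labels_by_stimulus,
                            average = "logits") {
  stims <- unique(records$stimulus_id)
  K <- ncol(records$logits)
  probs <- matrix(NA_real_, length(stims), K)
  pred <- integer(length(stims))
  for (i in seq_along(stims)) {
    cp <- consensus_predict(records[records$stimulus_id == stims[i], ],
                            average = average)
    probs[i, ] <- cp$probabilities
    pred[i] <- cp$predicted_class
  }
  list(stimulus_id = stims, probabilities = probs, predicted = pred,
       labels = labels_by_stimulus[stims])
}

#' Consensus accuracy as a function of the number of subjects
#'
#' For each subset size n in `n_grid`, repeatedly draws random size-n subject
#' subsets per test stimulus, forms the consensus prediction, and reports
#' the mean and spread of test accuracy over the resamples. When n equals
#' every stimulus's full subject count the point is deterministic.
#'
#' @param records [logits_records()] for the test stimuli.
#' @param labels named integer vector: ground-truth class per stimulus_id.
#' @param n_grid subset sizes to evaluate.
#' @param resamples random subsets per size.
#' @param seed integer seed for the subset draws.
#' @param cap if TRUE (default), n is capped per stimulus at the number of
#'   subjects who watched it; if FALSE, an over-large n is an error.
#' @return Tibble: n_subjects, mean_accuracy, sd_accuracy.
#' @export
accuracy_vs_n_subjects <- function(records, labels,
                                   n_grid = c(1, 2, 5, 10, 15, 20, 25),
                                   resamples = 20, seed = 1, cap = TRUE) {
  stims <- unique(records$stimulus_id)
  subj_by_stim <- lapply(stims, function(s)
    unique(records$subject_id[records$stimulus_id == s]))
  names(subj_by_stim) <- stims
  avail <- vapply(subj_by_stim, length, integer(1))
  if (!cap && any(n_grid > min(avail))) {
    stopf("n = %d exceeds the %d subjects available for some stimulus",
          max(n_grid), min(avail))
  }
  ## per-stimulus logit matrices (original row order preserved), so each
  ## resample reduces to a row subset + colMeans — the same arithmetic as
  ## consensus_predict without per-draw record subsetting
  Z_by_stim <- lapply(stims, function(s) {
    rows <- which(records$stimulus_id == s)
    list(Z = records$logits[rows, , drop = FALSE],
         subjects = records$subject_id[rows])
  })
  names(Z_by_stim) <- stims
  out <- vector("list", length(n_grid))
  for (gi in seq_along(n_grid)) {
    n <- n_grid[gi]
    accs <- numeric(resamples)
    deterministic <- all(pmin(n, avail) == avail)
    reps <- if (deterministic) 1L else resamples
    for (r in seq_len(reps)) {
      correct <- 0L
      for (s in stims) {
        pool <- subj_by_stim[[s]]
        k <- min(n, length(pool))
        pick <- if (k == length(pool)) pool else
          with_seed(derive_seed(seed, gi, r, match(s, stims)),
                    sample(pool, k))
        zs <- Z_by_stim[[s]]
        ml <- colMeans(zs$Z[zs$subjects %in% pick, , drop = FALSE])
        if (argmax1(ml) - 1L == labels[[s]]) correct <- correct + 1L
      }
      accs[r] <- correct / length(stims)
    }
    if (deterministic) accs <- rep(accs[1], resamples)
    out[[gi]] <- tibble::tibble(n_subjects = n,
                                mean_accuracy = mean(accs[seq_len(reps)]),
                                sd_accuracy = if (reps > 1)
                                  stats::sd(accs[seq_len(reps)]) else 0)
  }
  do.call(rbind, out)
}

#' Trapezoidal one-vs-rest ROC AUC
#'
#' AUC of the ROC curve for a binary problem by the trapezoidal rule over
#' score thresholds; ties produce diagonal segments, so the value equals the
#' normalised concordance count with ties worth 1/2.
#'
#' @param scores numeric scores, higher = more positive.
#' @param positive logical (or 0/1) vector marking positives.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]; pos <- positive[ord]
  ## walk thresholds at distinct score values; trapezoid over (FPR, TPR)
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Per-class one-vs-rest ROC/AUC table
#'
#' Each class's softmax score is scored against the one-vs-rest labels;
#' classes absent from the labels get `NA` (flagged), and the macro average
#' is taken over the defined classes.
#'
#' @param probabilities instances x n_classes score matrix (softmax scores
#'   or any monotone class score).
#' @param labels integer ground-truth labels in `[0, n_classes)`.
#' @return List: `per_class` tibble (class, auc, n_pos), `macro_auc`.
#' @export
per_class_roc <- function(probabilities, labels) {
  stopifnot(is.matrix(probabilities), nrow(probabilities) == length(labels))
  K <- ncol(probabilities)
  auc <- n_pos <- numeric(K)
  for (k in seq_len(K)) {
    pos <- labels == (k - 1L)
    n_pos[k] <- sum(pos)
    auc[k] <- roc_auc(probabilities[, k], pos)
  }
  if (any(is.na(auc))) {
    warning(sprintf("AUC undefined for class(es) absent from labels: %s",
                    paste(which(is.na(auc)) - 1L, collapse = ", ")),
            call. = FALSE)
  }
  list(per_class = tibble::tibble(class = seq_len(K) - 1L, auc = auc,
                                  n_pos = as.integer(n_pos)),
       macro_auc = mean(auc, na.rm = TRUE))
}
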