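#' Temperature-smoothed teacher soft labels
#'
#' For every training stimulus, the teacher distribution is the softmax at
#' temperature T of the consensus (subject-averaged) teacher logits:
#' `s_i = softmax(mean_logits_i / T)`.
#'
#' @param records teacher [logits_records()] covering all requested stimuli.
#' @param stimulus_ids stimuli to cover, in output order.
#' @param temperature softmax temperature T > 0.
#' @return A `soft_label_set`: list with `stimulus_id`, `soft` (stimuli x
#'   n_classes matrix, rows summing to 1), `temperature`.
#' @export
make_teacher_soft_labels <- function(records, stimulus_ids, temperature = 1) {
  missing <- setdiff(stimulus_ids, unique(records$stimulus_id))
  if (length(missing) > 0) {
    stopf("no teacher records for stimulus(es): %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  K <- ncol(records$logits)
  soft <- matrix(NA_real_, length(stimulus_ids), K)
  for (i in seq_along(stimulus_ids)) {
    cp <- consensus_predict(
      records[records$stimulus_id == stimulus_ids[i], ])
    soft[i, ] <- softmax(cp$mean_logits, temperature)
  }
  structure(list(stimulus_id = stimulus_ids, soft = soft,
                 temperature = temperature),
            class = "soft_label_set")
}

#' Generalized-distillation objective
#'
#' The per-batch loss `(1/n) sum_i [(1-lambda) l(y_i, p_i) + lambda
#' l(s_i, p_i)]` with `l` the cross-entropy (soft-target cross-entropy for
#' the teacher term) and `p_i = softmax(z_i)` the student's class
#' distribution. At `lambda = 0` this is plain cross-entropy on the hard
#' labels; at `lambda = 1` the hard labels drop out entirely.
#'
#' @param student_logits instances x n_classes matrix of student logits z.
#' @param y integer hard labels in `[0, n_classes)`.
#' @param soft instances x n_classes matrix of teacher distributions s.
#' @param lambda imitation factor in `[0, 1]`.
#' @return Scalar loss (nats).
#' @export
distill_loss <- function(student_logits, y, soft, lambda) {
  if (lambda < 0 || lambda > 1) stopf("lambda must be in [0, 1]")
  n <- nrow(student_logits)
  p <- softmax(student_logits)
  hard <- -mean(log(p[cbind(seq_len(n), as.integer(y) + 1L)]))
  soft_term <- -mean(rowSums(soft * log(p)))
  (1 - lambda) * hard + lambda * soft_term
}

#' @rdname distill_loss
#' @return `distill_loss_grad`: instances x n_classes gradient of the loss
#'   with respect to the student logits (`(p - t)/n` with the mixed target
#'   `t = (1-lambda) onehot(y) + lambda s`).
#' @export
distill_loss_grad <- function(student_logits, y, soft, lambda) {
  n <- nrow(student_logits)
  K <- ncol(student_logits)
  onehot <- matrix(0, n, K)
  onehot[cbind(seq_len(n), as.integer(y) + 1L)] <- 1
  target <- (1 - lambda) * onehot + lambda * soft
  (softmax(student_logits) - target) / n
}

#' Train a video-only student under teacher supervision
#'
#' Minimises the generalized-distillation objective over the student's
#' parameters; the student sees video features only — the EEG modality
#' enters solely through the teacher's soft labels.
#'
#' @param spec a [classifier_spec()] of a gradient-trained kind
#'   (`linear_student` or `de_mlp`).
#' @param x instances x features matrix of video features.
#' @param y integer hard labels.
#' @param soft_labels a `soft_label_set` (or instances x n_classes matrix)
#'   aligned with the rows of `x`.
#' @param lambda imitation factor in `[0, 1]`.
#' @param stimulus_ids when `soft_labels` is a `soft_label_set`, the
#'   stimulus of each row of `x`, used for alignment.
#' @return A trained `eeg_classifier`.
#' @export
distill_student <- function(spec, x, y, soft_labels, lambda,
                            stimulus_ids = NULL) {
  if (lambda < 0 || lambda > 1) stopf("lambda must be in [0, 1]")
  if (inherits(soft_labels, "soft_label_set")) {
    if (is.null(stimulus_ids)) {
      stopf("stimulus_ids required to align a soft_label_set with x")
    }
    idx <- match(stimulus_ids, soft_labels$stimulus_id)
    if (anyNA(idx)) stopf("soft labels missing for some stimuli")
    soft <- soft_labels$soft[idx, , drop = FALSE]
  } else {
    soft <- soft_labels
  }
  if (nrow(soft) != nrow(x)) stopf("soft labels misaligned with x")
  train_classifier(spec, x, y, soft_targets = soft, imitation = lambda)
}

#' Sweep the temperature / imitation-factor grid
#'
#' For every (T, lambda) cell, trains `n_runs` students from independent
#' seeds, recording validation and test accuracy; reports per-cell mean and
#' standard deviation and the cell selected by validation accuracy.
#'
#' @param teacher_records teacher [logits_records()] covering train and
#'   validation stimuli.
#' @param video_features stimuli x features matrix (rownames = stimulus_id).
#' @param labels named integer vector of class labels per stimulus_id.
#' @param split a `dataset_split` from [make_split()].
#' @param temperatures,lambdas grid values (defaults: the conventional
#'   6 x 4 grid).
#' @param n_runs independent seeds per cell.
#' @param spec student [classifier_spec()]; its seed is re-derived per run.
#' @param seed base seed for the runs.
#' @return List: `grid` tibble (temperature, lambda, mean/sd of val and test
#'   accuracy), `best` (validation-selected row), `baseline` (lambda = 0
#'   student, same protocol).
#' @export
run_grid <- function(teacher_records, video_features, labels, split,
                     temperatures = c(1, 2, 5, 10, 20, 50),
                     lambdas = c(0.25, 0.5, 0.75, 1),
                     n_runs = 5, spec = NULL, seed = 1) {
  stopifnot(inherits(split, "dataset_split"))
  if (is.null(spec)) {
    spec <- classifier_spec("linear_student",
                            n_classes = max(labels) + 1L,
                            epochs = 200, batch_size = 32, seed = 1)
  }
  tr <- split$train_stimuli; va <- split$val_stimuli; te <- split$test_stimuli
  xtr <- video_features[tr, , drop = FALSE]
  scaler <- fit_scaler(xtr)
  xtr <- apply_scaler(scaler, xtr)
  xva <- apply_scaler(scaler, video_features[va, , drop = FALSE])
  xte <- apply_scaler(scaler, video_features[te, , drop = FALSE])
  ytr <- labels[tr]; yva <- labels[va]; yte <- labels[te]

  eval_student <- function(lambda, soft, run_seed) {
    sp <- spec; sp$seed <- run_seed
    mdl <- if (lambda == 0) {
      train_classifier(sp, xtr, ytr)
    } else {
      distill_student(sp, xtr, ytr, soft, lambda)
    }
    c(val = mean(predict(mdl, xva) == yva),
      test = mean(predict(mdl, xte) == yte))
  }

  cells <- expand.grid(temperature = temperatures, lambda = lambdas,
                       KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(cells))
  soft_by_T <- list()
  for (ci in seq_len(nrow(cells))) {
    Tv <- cells$temperature[ci]; lv <- cells$lambda[ci]
    key <- as.character(Tv)
    if (is.null(soft_by_T[[key]])) {
      sl <- make_teacher_soft_labels(teacher_records, tr, Tv)
      soft_by_T[[key]] <- sl$soft
    }
    acc <- vapply(seq_len(n_runs), function(r)
      eval_student(lv, soft_by_T[[key]], derive_seed(seed, 100L, r)),
      numeric(2))
    res[[ci]] <- tibble::tibble(
      temperature = Tv, lambda = lv,
      val_mean = mean(acc["val", ]), val_sd = stats::sd(acc["val", ]),
      test_mean = mean(acc["test", ]), test_sd = stats::sd(acc["test", ]))
  }
  grid <- do.call(rbind, res)
  if (n_runs == 1) grid$val_sd <- grid$test_sd <- 0
  ## the baseline shares each run's training seed with the grid cells
  ## (common random numbers): the distilled-minus-baseline contrast then
  ## isolates the soft-label effect from initialisation/shuffling noise
  base_acc <- vapply(seq_len(n_runs), function(r)
    eval_student(0, NULL, derive_seed(seed, 100L, r)), numeric(2))
  baseline <- tibble::tibble(
    temperature = NA_real_, lambda = 0,
    val_mean = mean(base_acc["val", ]),
    val_sd = if (n_runs > 1) stats::sd(base_acc["val", ]) else 0,
    test_mean = mean(base_acc["test", ]),
    test_sd = if (n_runs > 1) stats::sd(base_acc["test", ]) else 0)
  ## stable sort: ties in validation accuracy resolve to the earliest grid
  ## cell (lowest T, then lowest lambda) — never by peeking at test
  best <- grid[order(-grid$val_mean), ][1, ]
  list(grid = grid, best = best, baseline = baseline)
}
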