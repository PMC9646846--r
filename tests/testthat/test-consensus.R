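records_for <- function(stimulus, logits_by_subject, class_label = 0L) {
  subj <- names(logits_by_subject)
  logits_records(model_id = paste0("m_", subj),
                 subject_id = subj,
                 stimulus_id = rep(stimulus, length(subj)),
                 logits_matrix = do.call(rbind, logits_by_subject),
                 class_label = rep(class_label, length(subj)))
}

test_that("consensus of one subject is that subject's softmaxed prediction", {
  r <- records_for("V1", list(a = c(1.2, -0.3, 0.7)))
  cp <- consensus_predict(r)
  expect_equal(cp$probabilities, softmax(c(1.2, -0.3, 0.7)))
  expect_equal(cp$mean_logits, c(1.2, -0.3, 0.7))
  expect_equal(cp$subject_ids_used, "a")
})

test_that("consensus averages logits, softmaxes, and tie-breaks low", {
  r <- records_for("V1", list(a = c(1, 0, 0), b = c(0, 1, 0)))
  cp <- consensus_predict(r)
  expect_equal(cp$mean_logits, c(0.5, 0.5, 0))
  expect_equal(cp$predicted_class, 0L)
  expect_equal(sum(cp$probabilities), 1)
  # subject order is irrelevant
  r2 <- records_for("V1", list(b = c(0, 1, 0), a = c(1, 0, 0)))
  expect_equal(consensus_predict(r2)$probabilities, cp$probabilities)
  # probability averaging is available as the alternative reading
  cp_p <- consensus_predict(r, average = "probabilities")
  expect_equal(cp_p$probabilities,
               colMeans(rbind(softmax(c(1, 0, 0)), softmax(c(0, 1, 0)))))
})

test_that("consensus rejects mixed stimuli and empty subsets", {
  r <- rbind(records_for("V1", list(a = c(1, 0))),
             records_for("V2", list(a = c(1, 0))))
  class(r) <- c("logits_records", class(tibble::tibble()))
  expect_error(consensus_predict(r), "mix")
  r1 <- records_for("V1", list(a = c(1, 0)))
  expect_error(consensus_predict(r1, subset = character(0)), "empty")
  expect_error(consensus_predict(r1, subset = "zz"), "no records")
})

test_that("accuracy curve is deterministic at full subject count", {
  set.seed(10)
  subj <- sprintf("s%d", 1:6)
  recs <- do.call(rbind, lapply(c("V1", "V2"), function(v)
    records_for(v, setNames(lapply(subj, function(s) rnorm(4)), subj),
                class_label = 1L)))
  class(recs) <- c("logits_records", class(tibble::tibble()))
  labels <- c(V1 = 1L, V2 = 1L)
  curve <- accuracy_vs_n_subjects(recs, labels, n_grid = c(2, 6),
                                  resamples = 5, seed = 1)
  expect_equal(curve$sd_accuracy[curve$n_subjects == 6], 0)
  expect_error(accuracy_vs_n_subjects(recs, labels, n_grid = c(10),
                                      resamples = 2, seed = 1, cap = FALSE),
               "exceeds")
  # capped: n = 10 falls back to the 6 available subjects
  capped <- accuracy_vs_n_subjects(recs, labels, n_grid = c(10),
                                   resamples = 2, seed = 1)
  expect_equal(capped$mean_accuracy,
               curve$mean_accuracy[curve$n_subjects == 6])
})

test_that("ROC AUC matches the all-pairs concordance oracle, ties included", {
  set.seed(11)
  for (rep in 1:20) {
    scores <- sample(seq(0, 1, by = 0.1), 25, replace = TRUE)  # many ties
    pos <- runif(25) < 0.4
    if (sum(pos) == 0 || sum(pos) == 25) next
    expect_equal(roc_auc(scores, pos), auc_concordance(scores, pos),
                 tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(3, 2, 1), c(TRUE, FALSE, FALSE)), 1.0)
  expect_true(is.na(roc_auc(c(1, 2), c(TRUE, TRUE))))
})

test_that("ROC AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- rnorm(60)
  pos <- rbinom(60, 1, 0.5)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    pos, scores, quiet = TRUE, direction = "<", levels = c(0, 1)))))
  expect_equal(roc_auc(scores, pos), ref, tolerance = 1e-10)
})

test_that("per-class ROC reports macro average and flags absent classes", {
  set.seed(13)
  n <- 80
  labels <- sample(0:2, n, replace = TRUE)
  probs <- softmax(matrix(rnorm(n * 4), n) +
                     2 * cbind(labels == 0, labels == 1, labels == 2, 0))
  expect_warning(per_class_roc(probs, labels), "absent")
  res <- suppressWarnings(per_class_roc(probs, labels))
  expect_equal(nrow(res$per_class), 4)
  expect_true(all(res$per_class$auc[1:3] > 0.5))
  expect_true(is.na(res$per_class$auc[4]))        # class 3 never occurs
  expect_equal(res$macro_auc, mean(res$per_class$auc[1:3]))
  # chance-level scores give AUC near 0.5
  flat <- per_class_roc(softmax(matrix(rnorm(400 * 3), 400)),
                        sample(0:2, 400, replace = TRUE))
  expect_lt(max(abs(flat$per_class$auc - 0.5)), 0.12)
})

test_that("perfectly separated scores give unit AUC per class", {
  labels <- rep(0:1, each = 10)
  probs <- cbind(rep(c(0.9, 0.1), each = 10), rep(c(0.1, 0.9), each = 10))
  res <- per_class_roc(probs, labels)
  expect_equal(res$per_class$auc, c(1, 1))
})
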