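#!/usr/bin/env Rscript

# Stage 3: subjects' consensus on the full default design.
#
# Trains one DE+MLP per subject, then averages logits across the subjects
# who watched each test stimulus. Writes the accuracy-versus-subjects curve
# (the consensus effect: accuracy rises steeply up to ~10 subjects, then
# plateaus), the per-class ROC/AUC with and without consensus, and the
# headline accuracy table. Figures are emitted when ggplot2 is available.

library(eegconsensus)

seed <- 1
out_dir <- "results/03_consensus"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(seed = seed)
run <- run_pipeline(cfg, resamples = 20, with_distillation = FALSE,
                    curve = TRUE)
write_pipeline_report(run, out_dir)

cat("Headline accuracies:\n")
print(as.data.frame(run$accuracy), row.names = FALSE)
cat("\nConsensus curve:\n")
print(as.data.frame(run$curve), row.names = FALSE)
cat(sprintf("\nMacro AUC: single-subject %.3f -> consensus %.3f\n",
            run$roc_single$macro_auc, run$roc_consensus$macro_auc))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(run$curve, aes(factor(n_subjects), mean_accuracy)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = mean_accuracy - sd_accuracy,
                      ymax = mean_accuracy + sd_accuracy), width = 0.2) +
    labs(x = "subjects averaged", y = "test accuracy",
         title = "Subjects' consensus: accuracy vs number of subjects") +
    theme_minimal()
  ggsave(file.path(out_dir, "consensus_curve.png"), p,
         width = 6, height = 4, dpi = 150)
  auc <- rbind(cbind(run$roc_single$per_class, mode = "single subject"),
               cbind(run$roc_consensus$per_class, mode = "consensus"))
  p2 <- ggplot(auc, aes(factor(class), auc, fill = mode)) +
    geom_col(position = "dodge") +
    labs(x = "class", y = "one-vs-rest AUC",
         title = "Per-class AUC with and without subjects' consensus") +
    theme_minimal()
  ggsave(file.path(out_dir, "per_class_auc.png"), p2,
         width = 7, height = 4, dpi = 150)
}
cat("Wrote", out_dir, "\n")
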