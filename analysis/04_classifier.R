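#!/usr/bin/env Rscript
# Step 4 -- multinomial logistic-regression density classifier.
#
# Stratified 70/30 split of the step-2 feature table, maximum-likelihood
# multinomial fit (softmax link, reference class a, ridge 1e-4), confusion
# matrices and per-class recalls on both partitions, plus a permuted-label
# control that must collapse to chance (25% for four balanced classes).

suppressMessages(library(bcttexture))

tb <- read_feature_table("results/feature_table.csv")

ev <- evaluate_classifier(tb, texture_feature_names(), train_frac = 0.7,
                          seed = 4L)
cat("test-set confusion matrix (rows = true class):\n")
print(ev$test_confusion)
cat(sprintf("\ntrain accuracy: %.1f%%   test accuracy: %.1f%%\n",
            ev$train_metrics$overall, ev$test_metrics$overall))
cat("per-class test recall (%):\n")
print(ev$test_metrics$recall_rounded)

set.seed(4)
tbp <- tb
tbp$density <- sample(tbp$density)
evp <- evaluate_classifier(tbp, texture_feature_names(), train_frac = 0.7,
                           seed = 4L)
cat(sprintf("\npermuted-label control test accuracy: %.1f%% (chance 25%%)\n",
            evp$test_metrics$overall))

dir.create("results/classifier", recursive = TRUE, showWarnings = FALSE)
write_density_model(ev$model, "results/classifier/model.json")
write.csv(as.matrix(ev$test_confusion), "results/classifier/test_confusion.csv")
jsonlite::write_json(
  list(train = ev$train_metrics, test = ev$test_metrics,
       permuted_test = evp$test_metrics),
  "results/classifier/metrics.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/classifier/\n")
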