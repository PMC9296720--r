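#!/usr/bin/env Rscript
# Step 2 -- extract the 19 texture features per examination.
#
# Streams a balanced phantom cohort under the study conditions (50 coronal
# slices per exam, 0.3 mm pixels, 5 mm skin margin, 64 grey levels, GLCM
# distance 1 and four in-plane directions) and writes the examinations x
# features table. 25 exams per class keeps this step at a few minutes of
# desk time while leaving every class well populated.

suppressMessages(library(bcttexture))

n_per_class <- 25L
cfg <- phantom_config()

cat("extracting features for", 4 * n_per_class, "examinations ...\n")
t0 <- proc.time()
tb <- build_feature_table(cfg, n_per_class, seed = 11L)
cat(sprintf("done in %.1f min\n", (proc.time() - t0)[3] / 60))

dir.create("results", showWarnings = FALSE)
write_feature_table(tb, "results/feature_table.csv")
cat("wrote results/feature_table.csv:", nrow(tb), "rows x",
    length(texture_feature_names()), "features\n\n")

cat("class means of the two headline features:\n")
print(round(rbind(skewness = tapply(tb$skewness, tb$density, mean),
                  GLN = tapply(tb$GLN, tb$density, mean)), 3))
cat("\nSkewness falls monotonically with density: low-density breasts pile",
    "\nmass at the fat peak (long right tail), dense breasts mirror it.\n")
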