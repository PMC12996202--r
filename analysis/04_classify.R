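#!/usr/bin/env Rscript
# Stage 4: nested cross-validated classification.
#
# Evaluates five classifier families (SVM, random forest, extra trees,
# AdaBoost over stumps, kNN) on the 15 movement features with stratified
# 5x5 nested CV, reports pooled out-of-fold metrics with Wilson
# intervals, both AUC conventions, permutation feature importance, and
# the age+sex-only SVM baseline.

suppressPackageStartupMessages(library(povmotion))

seed <- 1L
features <- read_features("results/features.csv")
ml <- run_ml_stage(features, cv_config(seed = seed))

tab <- ml$table
cat("model performance (pooled out-of-fold):\n")
print(data.frame(model = tab$model,
                 accuracy_pct = round(100 * tab$accuracy, 2),
                 mean_fold_auc = round(tab$mean_fold_auc, 2),
                 pooled_auc = round(tab$pooled_auc, 2)),
      row.names = FALSE)
best <- tab$model[which.max(tab$pooled_auc[tab$model != "demographic_baseline"])]
cat(sprintf("best movement model by pooled AUC: %s\n", best))

pfi_svm <- ml$pfi[ml$pfi$model == "svm", ]
pfi_svm <- pfi_svm[order(-pfi_svm$importance), ][1:5, ]
cat("top SVM permutation importances:\n")
print(pfi_svm[, c("feature", "importance")], row.names = FALSE, digits = 3)

data.table::fwrite(tab, "results/ml_report.csv")
jsonlite::write_json(tab, "results/ml_report.json", dataframe = "rows",
                     digits = NA)
data.table::fwrite(ml$pfi, "results/pfi.csv")
data.table::fwrite(ml$roc_points, "results/roc_points.csv")
cat("wrote results/ml_report.{csv,json}, results/pfi.csv, results/roc_points.csv\n")
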