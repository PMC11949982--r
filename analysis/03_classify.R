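#!/usr/bin/env Rscript
# Step 3: classification experiments and ROC inference.
#
# Reads the step-2 feature table and runs the six experiments (three
# feature sets x multiclass/binary): stratified 10-fold CV with SMOTE on
# training folds, 100-tree random forests, per-class AUROC with 2,000-rep
# bootstrap CIs, DeLong comparisons between feature sets (BH-corrected),
# impurity-based importance ranking, and a 20-permutation null
# calibration.

suppressPackageStartupMessages(library(osahrv))
dir.create("results", showWarnings = FALSE)

SEED <- 2024
tab <- read.csv("results/feature_table.csv", check.names = FALSE,
                stringsAsFactors = FALSE)

sets <- c(hrv = "hrv", spo2 = "spo2", all = "all")
auroc_rows <- list()
reports <- list(multiclass = list(), binary = list())
for (task in c("multiclass", "binary")) {
  for (fs in sets) {
    rep <- run_experiment(tab, experiment_spec(
      feature_set = fs, task = task, seed = SEED, bootstrap_reps = 2000))
    reports[[task]][[fs]] <- rep
    a <- rep$auroc
    a$task <- task; a$feature_set <- fs
    auroc_rows[[paste(task, fs)]] <- a
  }
}
auroc_tab <- do.call(rbind, auroc_rows)
rownames(auroc_tab) <- NULL
write.csv(auroc_tab, "results/auroc_table.csv", row.names = FALSE)

cmp <- rbind(
  cbind(task = "multiclass",
        pairwise_model_comparisons(reports$multiclass)),
  cbind(task = "binary", pairwise_model_comparisons(reports$binary)))
write.csv(cmp, "results/model_comparisons.csv", row.names = FALSE)

imp <- head(reports$binary$all$importance, 10)
imp_mc <- head(reports$multiclass$all$importance, 10)
write.csv(imp, "results/importance_binary_top10.csv", row.names = FALSE)
write.csv(imp_mc, "results/importance_multiclass_top10.csv",
          row.names = FALSE)

null_auc <- permutation_null_auroc(
  tab, experiment_spec(feature_set = "all", task = "binary", seed = SEED),
  n_perm = 20, seed = SEED)
write.csv(data.frame(perm = seq_along(null_auc), auroc = null_auc),
          "results/null_permutation_auroc.csv", row.names = FALSE)

cat("AUROC (95% bootstrap CI) by task and feature set:\n")
print(transform(auroc_tab,
                auroc = round(auroc, 3), ci_lo = round(ci_lo, 3),
                ci_hi = round(ci_hi, 3)), row.names = FALSE)
cat("\nOn this synthetic cohort the severity signal is strong enough that\n")
cat("all feature sets classify near-perfectly; label permutation collapses\n")
cat(sprintf("the binary AUROC to chance (mean %.3f over 20 permutations).\n",
            mean(null_auc)))
cat("\nTop-10 features, all-features binary model (% impurity decrease):\n")
print(transform(imp, pct = round(pct, 2)), row.names = FALSE)
cat("Wrote results/auroc_table.csv, model_comparisons.csv,\n")
cat("importance_*_top10.csv, null_permutation_auroc.csv\n")
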