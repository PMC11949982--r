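#' Specification of a classification experiment
#'
#' @param feature_set `"hrv"`, `"spo2"` or `"all"`; see
#'   [feature_set_columns()].
#' @param task `"multiclass"` (four severity classes) or `"binary"`
#'   (normal-to-mild vs moderate-to-severe, AHI cutoff 15).
#' @param n_trees random-forest trees.
#' @param cv_folds stratified cross-validation folds.
#' @param smote_k SMOTE nearest-neighbour count.
#' @param seed RNG seed fixing folds, SMOTE draws, forests and bootstrap.
#' @param bootstrap_reps bootstrap repetitions for the AUROC confidence
#'   interval; 0 skips the interval.
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(feature_set = c("all", "hrv", "spo2"),
                            task = c("multiclass", "binary"),
                            n_trees = 100, cv_folds = 10, smote_k = 5,
                            seed = 1, bootstrap_reps = 2000) {
  structure(list(feature_set = match.arg(feature_set),
                 task = match.arg(task),
                 n_trees = as.integer(n_trees),
                 cv_folds = as.integer(cv_folds),
                 smote_k = as.integer(smote_k),
                 seed = as.integer(seed),
                 bootstrap_reps = as.integer(bootstrap_reps)),
            class = "experiment_spec")
}

# fold id per row, stratified by class; errors if a class cannot reach
# every fold
stratified_folds <- function(y, k) {
  if (min(table(y)) < k)
    stop("stratification error: a class has fewer members than folds")
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' AUROC as the normalised Mann-Whitney U statistic of the scores, with
#' ties counted 1/2.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param positive logical vector marking positive cases.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Run one cross-validated classification experiment
#'
#' Stratified k-fold cross-validation with SMOTE applied inside the
#' training folds only (synthetic rows never reach a validation fold); a
#' random forest (no depth limit) per fold; out-of-fold class-probability
#' scores pooled over folds; one-vs-rest AUROC per class (a single AUROC
#' for the binary task) with a subject-level bootstrap percentile
#' confidence interval; and impurity-decrease feature importances from a
#' forest fit on the full SMOTE-balanced dataset, normalised to percent.
#'
#' @param table a feature table from [build_feature_table()].
#' @param spec an [experiment_spec()].
#' @return object of class `osa_model_report`: list with `auroc`
#'   (data.frame class/auroc/ci_lo/ci_hi), `importance` (data.frame
#'   feature/pct/rank), `scores` (out-of-fold probability matrix, one row
#'   per subject), `y`, `ids`, `folds` (list of per-fold validation row
#'   indices), `fold_info` (per-fold original/synthetic training counts)
#'   and `spec`.
#' @export
run_experiment <- function(table, spec = experiment_spec()) {
  stopifnot(inherits(spec, "experiment_spec"))
  set.seed(spec$seed)
  cols <- feature_set_columns(spec$feature_set)
  X <- table[, cols, drop = FALSE]
  y <- if (spec$task == "binary")
    factor(table$binary, levels = binary_levels)
  else
    factor(table$severity, levels = severity_levels)
  if (anyNA(y)) stop("missing class labels")
  keep <- complete.cases(X)
  if (!all(keep)) stop("feature table contains missing values")
  n <- nrow(X)
  folds <- stratified_folds(y, spec$cv_folds)
  scores <- matrix(NA_real_, n, nlevels(y),
                   dimnames = list(NULL, levels(y)))
  fold_list <- vector("list", spec$cv_folds)
  fold_info <- data.frame(fold = seq_len(spec$cv_folds),
                          n_train_original = NA_integer_,
                          n_train_synthetic = NA_integer_)
  for (f in seq_len(spec$cv_folds)) {
    tr <- folds != f
    sm <- smote_oversample(X[tr, , drop = FALSE], y[tr], k = spec$smote_k)
    fit <- randomForest::randomForest(x = sm$X, y = sm$y,
                                      ntree = spec$n_trees)
    scores[!tr, ] <- stats::predict(fit, X[!tr, , drop = FALSE],
                                    type = "prob")
    fold_list[[f]] <- which(!tr)
    fold_info$n_train_original[f] <- sum(!sm$synthetic)
    fold_info$n_train_synthetic[f] <- sum(sm$synthetic)
  }
  auc_tab <- experiment_auroc(scores, y, spec)
  sm_full <- smote_oversample(X, y, k = spec$smote_k)
  full_fit <- randomForest::randomForest(x = sm_full$X, y = sm_full$y,
                                         ntree = spec$n_trees)
  gini <- randomForest::importance(full_fit)[, "MeanDecreaseGini"]
  imp <- data.frame(feature = names(gini),
                    pct = 100 * gini / sum(gini),
                    row.names = NULL, stringsAsFactors = FALSE)
  imp <- imp[order(-imp$pct), ]
  imp$rank <- seq_len(nrow(imp))
  rownames(imp) <- NULL
  structure(list(auroc = auc_tab, importance = imp, scores = scores,
                 y = y, ids = table$id, folds = fold_list,
                 fold_info = fold_info, spec = spec),
            class = "osa_model_report")
}

# per-class one-vs-rest AUROC with subject-level bootstrap percentile CI
experiment_auroc <- function(scores, y, spec) {
  classes <- if (spec$task == "binary") binary_levels[2] else levels(y)
  point <- vapply(classes, function(cl)
    auroc(scores[, cl], y == cl), 0)
  ci <- matrix(NA_real_, length(classes), 2)
  if (spec$bootstrap_reps > 0) {
    n <- length(y)
    boot <- matrix(NA_real_, spec$bootstrap_reps, length(classes))
    for (b in seq_len(spec$bootstrap_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot[b, ] <- vapply(classes, function(cl)
        auroc(scores[idx, cl], y[idx] == cl), 0)
    }
    ci <- t(apply(boot, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  }
  data.frame(class = if (spec$task == "binary") "binary" else classes,
             auroc = unname(point), ci_lo = ci[, 1], ci_hi = ci[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.osa_model_report <- function(x, ...) {
  cat(sprintf("<osa_model_report> %s task, feature set '%s'\n",
              x$spec$task, x$spec$feature_set))
  print(x$auroc, digits = 3)
  cat("top features:",
      paste(head(x$importance$feature, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Mean AUROC under label permutation (null calibration)
#'
#' Repeats the full cross-validated experiment on copies of the feature
#' table whose class labels have been randomly permuted, breaking any
#' feature-label association. The mean AUROC over permutations calibrates
#' the pipeline's chance level.
#'
#' @param table a feature table.
#' @param spec an [experiment_spec()]; its bootstrap is skipped.
#' @param n_perm number of permutations.
#' @param seed RNG seed governing the permutations (each permutation run
#'   derives its own experiment seed).
#' @return numeric vector of AUROCs, one per permutation (for the
#'   multiclass task, the per-permutation mean over classes).
#' @export
permutation_null_auroc <- function(table, spec = experiment_spec(task = "binary"),
                                   n_perm = 20, seed = 1) {
  spec$bootstrap_reps <- 0L
  vapply(seq_len(n_perm), function(p) {
    set.seed((as.numeric(seed) * 7919 + p) %% 2147483647)
    perm <- sample.int(nrow(table))
    tab <- table
    tab$severity <- table$severity[perm]
    tab$binary <- table$binary[perm]
    sp <- spec
    sp$seed <- as.integer((as.numeric(seed) * 104729 + p) %% 2147483647)
    rep <- run_experiment(tab, sp)
    mean(rep$auroc$auroc)
  }, 0)
}
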