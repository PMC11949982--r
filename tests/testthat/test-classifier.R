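test_that("SMOTE synthesises points on segments between mutual neighbours", {
  set.seed(101)
  X <- data.frame(f1 = c(0, 1, rnorm(20, 10)), f2 = c(0, 1, rnorm(20, 10)))
  y <- c("min", "min", rep("maj", 20))
  sm <- suppressWarnings(smote_oversample(X, y, k = 5))
  expect_equal(as.vector(table(sm$y)), c(20, 20))
  syn <- sm$X[sm$synthetic, ]
  # A = (0,0), B = (1,1) are mutual neighbours: every synthetic point is
  # A + u (B - A), i.e. on the diagonal with coordinates in [0, 1]
  expect_equal(syn$f1, syn$f2, tolerance = 1e-12)
  expect_true(all(syn$f1 >= 0 & syn$f1 <= 1))
})

test_that("SMOTE balances the published class sizes 47/63/70/111 to 111", {
  set.seed(102)
  n <- c(47, 63, 70, 111)
  X <- data.frame(a = rnorm(sum(n)), b = rnorm(sum(n)))
  y <- rep(severity_levels, n)
  sm <- smote_oversample(X, y, k = 5)
  expect_equal(as.vector(table(sm$y)[severity_levels]), rep(111L, 4))
  expect_equal(sum(!sm$synthetic), sum(n))
  expect_equal(sm$X[!sm$synthetic, ], X, ignore_attr = TRUE)
})

test_that("balanced input passes through SMOTE unchanged", {
  X <- data.frame(a = rnorm(40))
  y <- rep(c("x", "y"), each = 20)
  sm <- smote_oversample(X, y)
  expect_equal(nrow(sm$X), 40)
  expect_false(any(sm$synthetic))
})

test_that("AUROC equals the normalised Mann-Whitney U, ties counted half", {
  set.seed(103)
  for (i in 1:10) {
    scores <- round(rnorm(40), 1)              # induce ties
    pos <- rbinom(40, 1, 0.4) == 1
    if (!any(pos) || all(pos)) next
    expect_equal(auroc(scores, pos), oracle_auroc(scores, pos),
                 tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under monotone score transformations", {
  set.seed(104)
  scores <- rnorm(60)
  pos <- rbinom(60, 1, 0.5) == 1
  expect_equal(auroc(scores, pos), auroc(exp(scores), pos))
  expect_equal(auroc(scores, pos), auroc(rank(scores), pos))
})

test_that("DeLong variance matches the looped structural components", {
  set.seed(105)
  for (i in 1:5) {
    pos <- c(rep(TRUE, 12), rep(FALSE, 18))    # 30-subject toy score set
    sa <- rnorm(30) + pos
    sb <- 0.6 * sa + 0.4 * rnorm(30)
    dl <- delong_test(sa, sb, pos)
    or <- oracle_delong(sa, sb, pos)
    expect_equal(dl$delta, or$delta, tolerance = 1e-10)
    expect_equal(dl$var_delta, or$var_delta, tolerance = 1e-10)
  }
})

test_that("identical score vectors compare as equal with p = 1", {
  set.seed(106)
  s <- rnorm(30)
  pos <- c(rep(TRUE, 10), rep(FALSE, 20))
  dl <- delong_test(s, s, pos)
  expect_equal(dl$delta, 0)
  expect_equal(dl$p, 1)
})

test_that("DeLong detects a genuinely better model", {
  set.seed(107)
  pos <- rep(c(TRUE, FALSE), each = 100)
  good <- rnorm(200) + 2 * pos
  bad <- rnorm(200)
  dl <- delong_test(good, bad, pos)
  expect_gt(dl$delta, 0.2)
  expect_lt(dl$p, 0.01)
})

test_that("the experiment is deterministic and leak-proof by construction", {
  tab <- make_toy_table(n = 140, seed = 108)
  sp <- experiment_spec(feature_set = "spo2", task = "binary", seed = 9,
                        bootstrap_reps = 100)
  rep1 <- run_experiment(tab, sp)
  rep2 <- run_experiment(tab, sp)
  expect_identical(rep1$auroc, rep2$auroc)
  expect_identical(rep1$importance, rep2$importance)
  # folds partition the subjects; every subject is scored exactly once
  all_idx <- sort(unlist(rep1$folds))
  expect_equal(all_idx, seq_len(nrow(tab)))
  expect_false(any(duplicated(unlist(rep1$folds))))
  expect_equal(nrow(rep1$scores), nrow(tab))
  expect_false(anyNA(rep1$scores))
  # SMOTE acts on training folds only: each fold's training set holds all
  # remaining original subjects plus synthetic rows, and validation scores
  # exist only for original subjects (the score matrix has no extra rows)
  for (f in seq_len(sp$cv_folds)) {
    expect_equal(rep1$fold_info$n_train_original[f],
                 nrow(tab) - length(rep1$folds[[f]]))
    expect_gte(rep1$fold_info$n_train_synthetic[f], 0)
  }
})

test_that("perfectly separable features reach AUROC 1 with a degenerate CI", {
  tab <- make_toy_table(n = 120, seed = 109, signal = 50)
  sp <- experiment_spec(feature_set = "spo2", task = "binary", seed = 4,
                        bootstrap_reps = 200)
  rep <- run_experiment(tab, sp)
  expect_equal(rep$auroc$auroc, 1)
  expect_equal(rep$auroc$ci_hi, 1)
  expect_equal(rep$auroc$ci_lo, 1)
})

test_that("multiclass reports carry one AUROC and CI per severity class", {
  tab <- make_toy_table(n = 160, seed = 110)
  sp <- experiment_spec(feature_set = "spo2", task = "multiclass", seed = 2,
                        bootstrap_reps = 100)
  rep <- run_experiment(tab, sp)
  expect_equal(rep$auroc$class, severity_levels)
  expect_true(all(rep$auroc$ci_lo <= rep$auroc$auroc + 1e-9))
  expect_true(all(rep$auroc$ci_hi >= rep$auroc$auroc - 1e-9))
  expect_equal(sum(rep$importance$pct), 100, tolerance = 1e-6)
  expect_equal(rep$importance$rank, seq_len(nrow(rep$importance)))
})

test_that("a class smaller than the fold count raises a stratification error", {
  tab <- make_toy_table(n = 30, seed = 111)
  tab$severity <- c("normal", rep(c("mild", "moderate", "severe"),
                                  length.out = 29))
  sp <- experiment_spec(feature_set = "spo2", task = "multiclass")
  expect_error(run_experiment(tab, sp), "stratification")
})

test_that("model comparison requires matched subjects and corrects p-values", {
  tab <- make_toy_table(n = 140, seed = 112)
  mk <- function(fs) run_experiment(
    tab, experiment_spec(feature_set = fs, task = "binary", seed = 3,
                         bootstrap_reps = 0))
  reps <- list(all = mk("all"), hrv = mk("hrv"), spo2 = mk("spo2"))
  cmp <- pairwise_model_comparisons(reps)
  expect_equal(nrow(cmp), 3)
  expect_true(all(cmp$p_corrected >= cmp$p_raw - 1e-12))
  expect_true(all(cmp$p_corrected <= 1))
  other <- make_toy_table(n = 140, seed = 999)
  rep_other <- run_experiment(other, experiment_spec(
    feature_set = "spo2", task = "binary", bootstrap_reps = 0))
  expect_error(compare_models(reps$all, rep_other), "same subjects")
})

test_that("cross-check: AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(113)
  scores <- rnorm(80)
  pos <- rbinom(80, 1, 0.5) == 1
  ref <- as.numeric(pROC::auc(pROC::roc(response = as.integer(pos),
                                        predictor = scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, pos), ref, tolerance = 1e-12)
})
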