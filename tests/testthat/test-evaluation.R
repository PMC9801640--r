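test_that("confusion counts the four cells with respect to the positive class", {
  truth <- rep(c("case", "ctrl"), c(7, 3))
  cm <- confusion(truth, truth, "case")
  expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]), c(TP = 7, TN = 3,
                                                        FP = 0, FN = 0))
  all_pos <- confusion(truth, rep("case", 10), "case")
  expect_equal(unlist(all_pos[c("TP", "FP", "TN", "FN")]),
               c(TP = 7, FP = 3, TN = 0, FN = 0))
  # order invariance
  o <- sample(10)
  cm2 <- confusion(truth[o], truth[o], "case")
  expect_equal(unclass(cm2), unclass(cm))
  expect_error(confusion(truth, truth[-1], "case"), "length")
  expect_error(confusion(truth, rep("oops", 10), "case"), "classes|unknown")
})

test_that("metrics match their closed forms, with 0/0 cells flagged as 0", {
  perfect <- classification_metrics(
    structure(list(TP = 10L, TN = 5L, FP = 0L, FN = 0L,
                   positive_class = "a"), class = "confusion_counts"))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$mcc, 1)

  m <- classification_metrics(
    structure(list(TP = 45L, TN = 30L, FP = 5L, FN = 10L,
                   positive_class = "a"), class = "confusion_counts"))
  expect_equal(m$mcc, 1300 / sqrt(3850000))
  expect_equal(m$sensitivity, 45 / 55)
  expect_equal(m$precision, 45 / 50)

  # harmonic-mean fixed point: recall = precision = 0.8 gives F = 0.8
  f <- classification_metrics(
    structure(list(TP = 40L, TN = 0L, FP = 10L, FN = 10L,
                   positive_class = "a"), class = "confusion_counts"))
  expect_equal(f$f_measure, 0.8)

  deg <- classification_metrics(
    structure(list(TP = 0L, TN = 5L, FP = 0L, FN = 0L,
                   positive_class = "a"), class = "confusion_counts"))
  expect_equal(deg$sensitivity, 0)
  expect_true(all(c("sensitivity", "precision", "mcc") %in% deg$degenerate))
})

test_that("MCC is invariant to the class designation and negated by flipped predictions", {
  set.seed(40)
  truth <- sample(c("a", "b"), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.3, "a", truth)
  m_a <- classification_metrics(confusion(truth, pred, "a"))
  m_b <- classification_metrics(confusion(truth, pred, "b"))
  expect_equal(m_a$mcc, m_b$mcc)       # designation swap: TP<->TN, FP<->FN
  expect_equal(m_a$sensitivity, m_b$specificity)
  flipped <- ifelse(pred == "a", "b", "a")
  m_f <- classification_metrics(confusion(truth, flipped, "a"))
  expect_equal(m_f$mcc, -m_a$mcc)      # inverting predictions negates MCC
})

test_that("rank-based AUC handles separation, ties and pair enumeration", {
  y <- c("pos", "pos", "neg", "neg")
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), y, "pos"), 1)
  expect_equal(auc_score(rep(0.5, 4), y, "pos"), 0.5)
  expect_equal(auc_score(c(0.9, 0.8, 0.3), c("pos", "neg", "pos"), "pos"), 0.5)
  # strictly increasing transform leaves AUC unchanged; pROC cross-check
  set.seed(8)
  sc <- runif(40); yy <- sample(c("pos", "neg"), 40, replace = TRUE)
  expect_equal(auc_score(sc, yy, "pos"), auc_score(qlogis(sc), yy, "pos"))
  ref <- as.numeric(pROC::auc(pROC::roc(yy, sc, levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc_score(sc, yy, "pos"), ref)
  expect_error(auc_score(sc, rep("pos", 40), "pos"), "both classes")
})

test_that("stratified folds partition exactly with balanced sizes and ratios", {
  labels <- rep(c("case", "ctrl"), c(249, 112))    # n = 361
  f <- stratified_folds(labels, 10, seed = 3)
  sizes <- tabulate(f, 10)
  expect_equal(sort(unique(sizes)), c(36L, 37L))
  expect_equal(sum(sizes), 361L)
  # per-fold case counts within one of the proportional share
  per_case <- vapply(1:10, function(k) sum(labels[f == k] == "case"),
                     integer(1))
  share <- 249 * sizes / 361
  expect_true(all(abs(per_case - share) <= 1))

  for (n in c(23, 100)) {
    lab <- rep(c("a", "b"), c(n - 11, 11))
    ff <- stratified_folds(lab, 5, seed = 1)
    expect_equal(sort(unique(ff)), 1:5)
    expect_equal(length(ff), n)
    expect_lte(diff(range(tabulate(ff, 5))), 1L)
  }
  expect_error(stratified_folds(rep(c("a", "b"), c(20, 3)), 5), "fewer rows")
})

test_that("cross-validation modes agree without resampling; constant learner bounds", {
  ds <- generate_imbalanced(60, 30, p = 2, class_sep = 2, seed = 10)
  learner <- function(d, s) train_tree(d, max_depth = 3)
  a <- cross_validate(ds, NULL, learner, folds = 5, mode = "paper_faithful",
                      seed = 4)
  b <- cross_validate(ds, NULL, learner, folds = 5, mode = "leakage_safe",
                      seed = 4)
  expect_equal(a$per_fold, b$per_fold)

  # a depth-0 stump always predicts the majority: sensitivity 0, specificity 1
  stump <- function(d, s) train_tree(d, max_depth = 0)
  r <- cross_validate(ds, NULL, stump, folds = 5, seed = 4)
  expect_equal(unname(r$mean["sensitivity"]), 0)
  expect_equal(unname(r$mean["specificity"]), 1)
})

test_that("leakage-safe resampling never alters test folds", {
  ds <- generate_imbalanced(60, 24, p = 2, class_sep = 1.5, seed = 12)
  res <- function(d, s) smote(d, resampler_config(seed = s))
  learner <- function(d, s) train_tree(d, max_depth = 3)
  r <- cross_validate(ds, res, learner, folds = 4, mode = "leakage_safe",
                      seed = 6)
  expect_equal(r$counts_after$n_minority, class_counts(ds)$n_minority)
  # paper-faithful mode evaluates on the resampled (balanced) data
  pf <- cross_validate(ds, res, learner, folds = 4, mode = "paper_faithful",
                       seed = 6)
  expect_equal(pf$counts_after$n_minority, pf$counts_after$n_majority)
})
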