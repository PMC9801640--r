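make_constant_tree <- function(label, positive_class, classes) {
  # a single-leaf stump predicting `label`, for hand-assembled ensembles
  structure(list(nodes = list(list(leaf = TRUE, pred = label,
                                   pos_frac = as.numeric(label == positive_class),
                                   n = 1L, n_pos = 0L, n_neg = 1L)),
                 root = 1L, positive_class = positive_class,
                 classes = classes, feature_names = "x1", p = 1L,
                 params = list(max_depth = 0L, min_samples_leaf = 1L, m = 1L)),
            class = "tree_model")
}

hand_ensemble <- function(labels, weights, positive = "pos",
                          classes = c("neg", "pos")) {
  members <- lapply(labels, make_constant_tree, positive_class = positive,
                    classes = classes)
  structure(list(members = members, weights = weights, rule = "bagging",
                 positive_class = positive, classes = classes, p = 1L,
                 feature_names = "x1", meta = list()),
            class = "ensemble_model")
}

test_that("ensemble voting follows the weighted argmax with positive-tie rule", {
  x <- matrix(0, 1, 1)
  expect_equal(predict(hand_ensemble(c("pos", "pos", "neg"), c(1, 1, 1)), x),
               "pos")
  un <- hand_ensemble(c("neg", "neg"), c(1, 1))
  expect_equal(predict(un, x, type = "both")$score, 0)
  expect_equal(predict(un, x), "neg")
  # AdaBoost-style weights: ln 3 for 'pos' beats ln 1.5 for 'neg'
  wv <- hand_ensemble(c("pos", "neg"), c(1.0986, 0.4055))
  expect_equal(predict(wv, x), "pos")
  expect_equal(predict(wv, x, type = "score"), 1.0986 / (1.0986 + 0.4055))
  # exact 0.5/0.5 tie goes to the positive class
  tie <- hand_ensemble(c("pos", "neg"), c(1, 1))
  expect_equal(predict(tie, x, type = "score"), 0.5)
  expect_equal(predict(tie, x), "pos")
})

test_that("bagging reduces to a single tree without bootstrap and is seeded", {
  ds <- random_dataset(50, 3, seed = 2, imbalance = 0.6)
  bag1 <- train_bagging(ds, T = 1, seed = 7, bootstrap = FALSE)
  tr <- train_tree(ds)
  expect_equal(predict(bag1, ds), predict(tr, ds))

  a <- train_bagging(ds, T = 9, seed = 7)
  b <- train_bagging(ds, T = 9, seed = 7)
  expect_identical(predict(a, ds, type = "score"),
                   predict(b, ds, type = "score"))
  c_ <- train_bagging(ds, T = 9, seed = 8)
  expect_false(identical(predict(a, ds, type = "score"),
                         predict(c_, ds, type = "score")))
})

test_that("random forest reduces to a tree at m = p and scores are vote shares", {
  ds <- random_dataset(40, 4, seed = 12, imbalance = 0.8)
  rf1 <- train_random_forest(ds, T = 1, m = 4, seed = 3, bootstrap = FALSE)
  expect_equal(predict(rf1, ds), predict(train_tree(ds), ds))
  rf <- train_random_forest(ds, T = 7, seed = 3)
  sc <- predict(rf, ds, type = "score")
  expect_true(all(sc >= 0 & sc <= 1))
  expect_true(all(abs(sc * 7 - round(sc * 7)) < 1e-9))   # votes / T
  expect_error(train_random_forest(ds, T = 3, m = 9), "m must be")
})

test_that("a random forest separates a linearly separable fixture perfectly", {
  set.seed(5)
  X <- rbind(matrix(rnorm(80, 0, 0.3), 40, 2),
             matrix(rnorm(40, 5, 0.3), 20, 2))
  ds <- labeled_dataset(X, rep(c("ctrl", "case"), c(40, 20)),
                        positive_class = "case")
  rf <- train_random_forest(ds, T = 101, seed = 13)
  expect_equal(mean(predict(rf, ds) == ds$labels), 1.0)
})

test_that("ensemble accuracy does not degrade as T grows", {
  ds <- generate_imbalanced(40, 20, p = 3, class_sep = 1.5, noise_frac = 0.05,
                            seed = 99)
  acc <- function(model) mean(predict(model, ds) == ds$labels)
  accs <- vapply(1:20, function(s) {
    c(acc(train_random_forest(ds, T = 1, seed = s)),
      acc(train_random_forest(ds, T = 15, seed = s)))
  }, numeric(2))
  expect_gte(mean(accs[2, ]), mean(accs[1, ]))
})

test_that("AdaBoost.M1 reproduces the hand-computed first round", {
  # stump errs on exactly one of four rows: eps = 1/4, beta = 1/3,
  # vote weight ln 3; the misclassified row's weight triples
  ds <- labeled_dataset(matrix(c(0, 1, 2, 3), ncol = 1),
                        c("A", "A", "B", "A"))
  ab <- train_adaboost(ds, T = 3, params = list(max_depth = 1))
  expect_equal(ab$meta$rounds$eps[1], 0.25)
  expect_equal(ab$meta$rounds$beta[1], 1/3)
  expect_equal(ab$weights[1], log(3), tolerance = 1e-12)
  expect_equal(ab$meta$rounds$w_next[[1]],
               c(0.25, 0.25, 0.25, 0.75) / 1.5, tolerance = 1e-12)
})

test_that("AdaBoost stops early on a perfect tree and flags degeneracy", {
  ds <- labeled_dataset(matrix(c(0, 1, 5, 6), ncol = 1),
                        c("A", "A", "B", "B"))
  ab <- train_adaboost(ds, T = 10)
  expect_length(ab$members, 1L)
  expect_equal(predict(ab, ds), predict(ab$members[[1]], ds))

  # identical features, balanced labels, depth-0 stump: eps = 1/2 at round 1
  flat <- labeled_dataset(matrix(1, 4, 1), c("A", "A", "B", "B"))
  dg <- train_adaboost(flat, T = 5, params = list(max_depth = 0))
  expect_true(dg$meta$degenerate)
  expect_equal(predict(dg, matrix(1, 1, 1)), "A")   # majority-class fallback
})

test_that("AdaBoost row weights stay a probability vector every round", {
  ds <- generate_imbalanced(30, 15, p = 2, class_sep = 1, noise_frac = 0.1,
                            seed = 17)
  ab <- train_adaboost(ds, T = 8, params = list(max_depth = 2))
  hist <- Filter(Negate(is.null), ab$meta$rounds$w_next)
  expect_gt(length(hist), 0L)
  for (w in hist) expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("models round-trip through JSON with identical predictions", {
  ds <- random_dataset(40, 3, seed = 6, imbalance = 0.5)
  rf <- train_random_forest(ds, T = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(rf, path)
  rf2 <- read_model_json(path)
  expect_identical(predict(rf2, ds, type = "both"),
                   predict(rf, ds, type = "both"))
  tr <- train_tree(ds, max_depth = 3)
  write_model_json(tr, path)
  expect_identical(predict(read_model_json(path), ds), predict(tr, ds))
})
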