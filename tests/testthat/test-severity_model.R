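test_that("fit_decision_tree finds the separating threshold in 1-D", {
  set.seed(71)
  x <- data.frame(m = c(rnorm(30, 0, 0.3), rnorm(30, 5, 0.3)))
  y <- rep(c("a", "b"), each = 30)
  tr <- fit_decision_tree(x, y, tree_params(minsplit = 20, cp = 0.01))
  expect_identical(nrow(tr$splits), 1L)
  expect_gt(tr$splits$threshold, max(x$m[1:30]))
  expect_lt(tr$splits$threshold, min(x$m[31:60]))
  expect_true(all(tr$rules$accuracy == 1))
  expect_identical(as.character(predict(tr, x)), y)
})

test_that("a prohibitive cp yields a root-only tree with a warning", {
  set.seed(72)
  x <- data.frame(m = rnorm(50))
  y <- rep(c("a", "b"), 25)
  expect_warning(tr <- fit_decision_tree(x, y, tree_params(cp = 0.99)), "single-leaf")
  expect_identical(nrow(tr$splits), 0L)
  expect_identical(tr$rules$rule, "<root>")
})

test_that("the tree recovers a two-marker split hierarchy", {
  # creatinine separates class 0 from {1, 2}; ALP separates 1 from 2
  set.seed(73)
  n <- 30
  tab <- data.frame(
    urinary_creatinine = c(rnorm(n, 14, 0.5), rnorm(2 * n, 9, 0.5)),
    alp = c(rnorm(n, 65, 5), rnorm(n, 80, 2), rnorm(n, 50, 2))
  )
  y <- rep(c("0", "1", "2"), each = n)
  tr <- fit_decision_tree(tab, y, tree_params(minsplit = 20, cp = 0.01))
  expect_identical(tr$splits$feature[1], "urinary_creatinine")
  expect_true("alp" %in% tr$splits$feature)
  expect_gt(mean(predict(tr, tab) == y), 0.95)
})

test_that("minsplit is respected", {
  set.seed(74)
  x <- data.frame(m = rnorm(12))
  y <- rep(c("a", "b"), 6)
  expect_warning(
    tr <- fit_decision_tree(x, y, tree_params(minsplit = 20, cp = 0.001)),
    "single-leaf")
  expect_identical(nrow(tr$splits), 0L)  # node of 12 < minsplit: no split
})

test_that("fit_rf separates a 3-IQR-shifted marker and ranks it first", {
  co <- make_separable_cohort(n_per_class = 40, seed = 12)
  m <- fit_rf(co[, default_feature_panel()], co$class3,
              rf_params(ntree = 300, seed = 1))
  expect_gt(1 - m$oob_error_overall, 0.90)
  expect_identical(m$ranking_gini[1], "urinary_creatinine")
  expect_identical(m$ranking_permutation[1], "urinary_creatinine")
})

test_that("fit_rf is at chance on permuted labels", {
  co <- make_separable_cohort(n_per_class = 40, seed = 13)
  set.seed(99)
  yperm <- sample(co$class3)
  m <- fit_rf(co[, default_feature_panel()], yperm, rf_params(ntree = 300, seed = 2))
  # majority class rate is 1/3 (balanced); allow generous Monte-Carlo noise
  expect_lt(1 - m$oob_error_overall, 0.45)
})

test_that("fit_rf validates inputs and is seed-reproducible", {
  co <- make_separable_cohort(n_per_class = 10, seed = 14)
  X <- co[, default_feature_panel()]
  expect_error(fit_rf(X, rep("a", nrow(X))), "2 classes")
  y2 <- co$class3; y2[co$class3 == 2] <- 1; y2[1] <- 2  # one lone class-2 case
  expect_error(fit_rf(X, y2), "imbalance")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_rf(Xna, co$class3), "missing values")

  m1 <- fit_rf(X, co$class3, rf_params(ntree = 50, seed = 5))
  m2 <- fit_rf(X, co$class3, rf_params(ntree = 50, seed = 5))
  expect_identical(m1$oob_predictions, m2$oob_predictions)
  expect_identical(m1$importance_gini, m2$importance_gini)
})

test_that("OOB bookkeeping identities hold", {
  co <- make_separable_cohort(n_per_class = 20, seed = 15)
  m <- fit_rf(co[, default_feature_panel()], co$class3, rf_params(ntree = 200, seed = 3))
  conf <- m$oob_confusion
  expect_equal(1 - sum(diag(conf)) / sum(conf), m$oob_error_overall)
  expect_equal(as.vector(rowSums(conf)), as.vector(table(m$labels)))
  expect_true(all(abs(rowSums(m$class_scores) - 1) < 1e-12))
})

test_that("correctly_predicted_subset keeps OOB-correct rows", {
  co <- make_separable_cohort(n_per_class = 30, seed = 16)
  m <- fit_rf(co[, default_feature_panel()], co$class3, rf_params(ntree = 300, seed = 4))
  sub <- suppressMessages(correctly_predicted_subset(m, co))
  expect_gt(nrow(sub), 0.9 * nrow(co))          # separable: nearly all retained
  expect_identical(
    nrow(sub),
    sum(!is.na(m$oob_predictions) & m$oob_predictions == m$labels))
  expect_error(correctly_predicted_subset(m, co[-1, ]), "does not match")

  # chance-level model keeps roughly n/k rows
  set.seed(77)
  yperm <- sample(co$class3)
  mp <- fit_rf(co[, default_feature_panel()], yperm, rf_params(ntree = 200, seed = 6))
  co_perm <- co; co_perm$class3 <- yperm
  subp <- suppressMessages(correctly_predicted_subset(mp, co_perm))
  expect_lt(abs(nrow(subp) / nrow(co) - 1 / 3), 0.15)
})

test_that("OOB error is seed-stable at large ntree on the separable cohort", {
  # the motivation for a large forest: ntree = 1000 stands in for the
  # production 5000 (stability only improves with more trees)
  co <- make_separable_cohort(n_per_class = 40, seed = 12)
  errs <- vapply(1:3, function(s) {
    fit_rf(co[, default_feature_panel()], co$class3,
           rf_params(ntree = 1000, seed = s))$oob_error_overall
  }, numeric(1))
  expect_lt(max(errs) - min(errs), 0.02)
})

test_that("cohen_kappa matches hand-computed values", {
  expect_equal(cohen_kappa(diag(c(10, 20, 30))), 1)
  marg <- outer(c(30, 70), c(30, 70)) / 100  # independence: kappa 0
  expect_equal(cohen_kappa(marg), 0)
  expect_equal(cohen_kappa(matrix(c(20, 10, 5, 15), 2)), 0.4)  # po=.7, pe=.5
  expect_error(cohen_kappa(matrix(0, 2, 2)), "zero total")
  expect_error(cohen_kappa(matrix(c(5, 0, 0, 0), 2)), "degenerate")
  expect_error(cohen_kappa(matrix(1, 2, 3)), "square")
})

test_that("compare_ensembles runs all methods and reflects separability", {
  co <- make_separable_cohort(n_per_class = 20, seed = 17)
  cmp <- compare_ensembles(co[, default_feature_panel()], co$class3,
                           cv_folds = 3, repeats = 1, seed = 2, rf_ntree = 100)
  expect_setequal(cmp$summary$method,
                  c("rf", "tree_boosting", "gradient_boosting", "svm"))
  expect_true(all(cmp$summary$mean_accuracy >= 0.9))

  set.seed(88)
  yperm <- sample(co$class3)
  cmpn <- compare_ensembles(co[, default_feature_panel()], yperm,
                            cv_folds = 3, repeats = 1, seed = 3, rf_ntree = 100)
  expect_true(all(abs(cmpn$summary$mean_kappa) < 0.3))

  single <- compare_ensembles(co[, default_feature_panel()], co$class3,
                              methods = "svm", cv_folds = 3, repeats = 1, seed = 4)
  expect_identical(unique(single$results$method), "svm")
  expect_error(compare_ensembles(co[, default_feature_panel()], co$class3,
                                 methods = "xgboost"), "unknown method")
})
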