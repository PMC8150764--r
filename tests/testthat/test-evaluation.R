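test_that("fold assignment is balanced, grouped and seeded", {
  ids <- sprintf("p%02d", 1:10)
  f <- assign_folds(ids, k = 5, seed = 3)
  expect_setequal(names(f), ids)
  expect_true(all(table(f) == 2))
  expect_identical(f, assign_folds(ids, 5, 3))
  expect_false(identical(unname(f), unname(assign_folds(ids, 5, 4))))
  expect_error(assign_folds(ids[1:4], k = 5), "at least 5")

  # uneven counts: sizes differ by at most one
  f2 <- assign_folds(sprintf("q%02d", 1:13), k = 5, seed = 1)
  expect_lte(diff(range(table(f2))), 1)
})

test_that("classification metrics match their closed forms", {
  expect_equal(f1_score(10, 0, 0), 1)
  expect_equal(f1_score(1, 1, 1), 0.5)
  expect_equal(f1_score(0, 5, 5), 0)
  expect_error(f1_score(-1, 0, 0), "non-negative")

  expect_equal(balanced_accuracy(10, 0, 10, 0), 1)
  expect_equal(balanced_accuracy(10, 10, 0, 0), 0.5)
  expect_equal(balanced_accuracy(8, 4, 6, 2), 0.7)
  expect_error(balanced_accuracy(0, 5, 5, 0), "absent")

  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(1, -1), c(0, 0)), 1)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_error(rmse(numeric(0), numeric(0)), "empty")

  expect_equal(macro_f1(c(1, 1, 1)), 1)
  expect_equal(macro_f1(c(0.2, 0.8)), 0.5)
  expect_equal(macro_f1(rep(0.37, 33)), 0.37)
})

test_that("AUC equals the pairwise rank statistic", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(auc(c(0.9, 0.8, 0.3), c(TRUE, FALSE, TRUE)), 0.5)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(14)
  for (i in 1:10) {
    sc <- round(runif(30), 2)           # rounding forces some ties
    lab <- runif(30) > 0.5
    if (any(lab) && any(!lab)) {
      expect_equal(auc(sc, lab), bf_auc(sc, lab))
    }
  }
})

test_that("nested CV is deterministic and accounts for every window", {
  coh <- small_cohort()
  ds <- build_task_dataset(coh$features, coh$roster, "type_binary",
                           target = "locomotion")
  grid2 <- list(list(max_depth = 2), list(max_depth = 8))
  cv1 <- nested_cv(ds, "decision_tree", grid = grid2, k = 5, seed = 21)
  cv2 <- nested_cv(ds, "decision_tree", grid = grid2, k = 5, seed = 21)
  expect_equal(cv1$folds, cv2$folds)
  expect_equal(cv1$confusion, cv2$confusion)

  # confusion row totals equal the dataset's per-class window counts
  expect_equal(as.vector(rowSums(cv1$confusion)),
               as.vector(table(ds$y)))
  expect_equal(sum(cv1$confusion), nrow(ds$x))
  expect_equal(nrow(cv1$folds), 5)

  # summary is the arithmetic mean/sd of the fold values
  expect_equal(cv1$summary$mean[cv1$summary$metric == "f1"],
               mean(cv1$folds$f1))
  expect_equal(cv1$summary$sd[cv1$summary$metric == "f1"],
               sd(cv1$folds$f1))
  # the inner loop chose one of the offered settings in every fold
  expect_true(all(cv1$folds$hyperparams %in%
                    c("max_depth=2", "max_depth=8")))
})

test_that("top feature ranking normalizes and honours n", {
  coh <- small_cohort()
  ds <- build_task_dataset(coh$features, coh$roster, "ee_regression")
  cv <- nested_cv(ds, "lasso", grid = reduced_grids()$lasso, k = 5, seed = 2)
  t15 <- top_features(cv, 15)
  expect_equal(nrow(t15), 15)
  t49 <- top_features(cv, 49)
  expect_equal(sum(t49$score), 1)
  expect_true(all(diff(t49$score) <= 0))
  expect_error(top_features(cv, 50), "exceeds")
})

test_that("a single informative feature is ranked first", {
  set.seed(6)
  n_part <- 10
  rows <- 40 * n_part
  x <- matrix(rnorm(rows * 49), rows, 49,
              dimnames = list(NULL, wpa_feature_names()))
  groups <- rep(sprintf("p%02d", 1:n_part), each = 40)
  y_num <- 2 + 3 * x[, "sdvm"] + rnorm(rows, 0, 0.1)
  ds <- structure(list(kind = "ee_regression", target = NULL, stratum = "all",
                       x = x, y = y_num, groups = groups, positive = NULL),
                  class = "wpa_task")
  cv <- nested_cv(ds, "xgboost", grid = reduced_grids()$xgboost, k = 5, seed = 9)
  expect_equal(top_features(cv, 1)$feature, "sdvm")
})
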