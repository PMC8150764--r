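# small helper: separable two-class data on one informative feature
sep_data <- function(n = 120, p = 6, seed = 4) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- factor(ifelse(x[, 1] > 0, "pos", "neg"), levels = c("neg", "pos"))
  x[, 1] <- x[, 1] + ifelse(y == "pos", 2, -2)
  list(x = x, y = y)
}

test_that("inverse-frequency class weights follow N / (K * N_c)", {
  expect_equal(compute_class_weights(rep(c("A", "B"), each = 50)),
               c(A = 1, B = 1))
  expect_equal(compute_class_weights(rep(c("A", "B"), c(90, 10))),
               c(A = 100 / 180, B = 5))
  expect_equal(compute_class_weights(rep(c("A", "B", "C"), c(1, 1, 2))),
               c(A = 4 / 3, B = 4 / 3, C = 2 / 3))
  expect_error(compute_class_weights(rep("A", 5)), "2 distinct")
})

test_that("every learner family fits, predicts and ranks features", {
  d <- sep_data()
  for (alg in c("decision_tree", "random_forest", "xgboost", "lasso")) {
    spec <- learner_spec(alg, "classification", seed = 2)
    m <- wpa_fit(spec, d$x, d$y)
    pr <- predict(m, d$x, type = "prob")
    expect_equal(dim(pr), c(nrow(d$x), 2))
    expect_true(all(pr >= 0 & pr <= 1))
    expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-6)
    cl <- predict(m, d$x, type = "class")
    expect_gt(mean(cl == d$y), 0.9)
    # importance contract: non-negative, sums to 1, informative feature on top
    expect_length(m$importance, ncol(d$x))
    expect_true(all(m$importance >= 0))
    expect_equal(sum(m$importance), 1)
    expect_equal(names(which.max(m$importance)), "f1")
  }
})

test_that("a separable decision tree reaches training F1 of 1", {
  d <- sep_data()
  m <- wpa_fit(learner_spec("decision_tree", "classification"), d$x, d$y)
  pred <- predict(m, d$x, type = "class")
  cm <- table(d$y, pred)
  expect_equal(f1_score(cm["pos", "pos"], cm["neg", "pos"], cm["pos", "neg"]), 1)
})

test_that("lasso regression recovers a known coefficient against least squares", {
  set.seed(8)
  n <- 400
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2 * x[, 1] + rnorm(n, 0, 0.01)
  m <- wpa_fit(learner_spec("lasso", "regression",
                            hyperparams = list(lambda = 1e-4)), x, y)
  # closed-form least squares as the oracle
  beta_ls <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
  expect_equal(beta_ls[2], 2, tolerance = 0.01)
  pred <- predict(m, x)
  expect_equal(pred, as.numeric(cbind(1, x) %*% beta_ls), tolerance = 0.02)
  expect_gt(m$importance["f1"], 0.95)
})

test_that("fits are deterministic under a fixed spec seed", {
  d <- sep_data(seed = 12)
  for (alg in c("random_forest", "xgboost")) {
    spec <- learner_spec(alg, "classification", seed = 99)
    p1 <- predict(wpa_fit(spec, d$x, d$y), d$x, type = "prob")
    p2 <- predict(wpa_fit(spec, d$x, d$y), d$x, type = "prob")
    expect_identical(p1, p2)
  }
})

test_that("integer case weights equal row duplication for the decision tree", {
  d <- sep_data(n = 60, seed = 3)
  w <- rep(c(2, 1), length.out = 60)
  spec <- learner_spec("decision_tree", "classification",
                       hyperparams = list(minsplit = 5))
  m_w <- wpa_fit(spec, d$x, d$y, case_weights = w)
  idx <- rep(seq_len(60), times = w)
  m_dup <- wpa_fit(spec, d$x[idx, ], d$y[idx])
  grid_x <- d$x
  expect_equal(predict(m_w, grid_x, type = "prob"),
               predict(m_dup, grid_x, type = "prob"), tolerance = 1e-9)
})

test_that("regression models beat the constant-mean predictor in-sample", {
  set.seed(21)
  n <- 200
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- 1.5 + x[, 2] - 0.5 * x[, 3] + rnorm(n, 0, 0.3)
  base_rmse <- rmse(rep(mean(y), n), y)
  for (alg in c("decision_tree", "random_forest", "xgboost", "lasso")) {
    m <- wpa_fit(learner_spec(alg, "regression", seed = 5), x, y)
    expect_lte(rmse(predict(m, x), y), base_rmse)
  }
})

test_that("invalid inputs are rejected", {
  d <- sep_data(n = 40)
  bad <- d$x; bad[1, 1] <- NA
  expect_error(wpa_fit(learner_spec("decision_tree"), bad, d$y), "non-finite")
  expect_error(wpa_fit(learner_spec("decision_tree"), d$x, d$y[-1]), "aligned")
  expect_error(wpa_fit(learner_spec("decision_tree"), d$x,
                       factor(rep("a", 40))), "2 classes")
  m <- wpa_fit(learner_spec("xgboost", "classification", seed = 1), d$x, d$y)
  expect_error(predict(m, d$x[, -1]), "missing feature")
})
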