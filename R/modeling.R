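#' Inverse-frequency class weights
#'
#' Weight for class c is `N / (K * N_c)` for N rows and K classes, so that
#' class weights are inversely proportional to class frequencies and a
#' balanced problem gets unit weights. Used to counter the strong class
#' imbalance of one-vs-rest activity tasks.
#'
#' @param labels Class label vector (>= 2 distinct classes).
#' @return Named numeric vector of per-class weights.
#' @export
compute_class_weights <- function(labels) {
  tab <- table(as.character(labels))
  if (length(tab) < 2) stop_input("need at least 2 distinct classes")
  n <- sum(tab)
  k <- length(tab)
  stats::setNames(as.numeric(n / (k * tab)), names(tab))
}

#' Learner specification
#'
#' One of the four learner families behind the uniform fit/predict
#' contract: CART decision tree, random forest, gradient boosting and the
#' lasso (L1-penalized logistic regression for classification, L1 linear
#' regression for the MET task).
#'
#' @param algorithm `"decision_tree"`, `"random_forest"`, `"xgboost"` or
#'   `"lasso"`.
#' @param task `"classification"` or `"regression"`.
#' @param hyperparams Named list; unset entries fall back to the family
#'   defaults (see [default_grids()] for the tuned names).
#' @param seed Integer seed making the fit deterministic.
#' @return An object of class `"wpa_learner_spec"`.
#' @export
learner_spec <- function(algorithm = c("decision_tree", "random_forest",
                                       "xgboost", "lasso"),
                         task = c("classification", "regression"),
                         hyperparams = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  task <- match.arg(task)
  structure(list(algorithm = algorithm, task = task,
                 hyperparams = hyperparams, seed = as.integer(seed)),
            class = "wpa_learner_spec")
}

#' Fit a learner
#'
#' Uniform fitting front end for the four learner families. Classification
#' models expose probability scores in [0, 1] (needed for AUC);
#' regression models predict METs. Per-row `case_weights` carry the
#' inverse-frequency class weights into every backend through the same
#' mechanism; pass `case_weights = compute_class_weights(y)[as.character(y)]`
#' to balance a classification fit. Fits are deterministic given
#' `spec$seed`.
#'
#' @param spec A [learner_spec()].
#' @param x Numeric feature matrix (or data frame), finite values only.
#' @param y Target: factor for classification, numeric for regression.
#' @param case_weights Optional per-row weights.
#' @return An object of class `"wpa_model"` with elements `spec`,
#'   `feature_names`, `classes` (classification) and `importance`
#'   (non-negative, sums to 1: impurity-based for the tree families,
#'   normalized absolute coefficients for the lasso).
#' @export
wpa_fit <- function(spec, x, y, case_weights = NULL) {
  stopifnot(inherits(spec, "wpa_learner_spec"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (!all(is.finite(x))) stop_input("feature matrix contains non-finite values")
  if (nrow(x) != length(y)) stop_input("x and y are not aligned")
  if (!is.null(case_weights) && length(case_weights) != length(y)) {
    stop_input("case_weights not aligned with y")
  }
  if (spec$task == "classification") {
    y <- if (is.factor(y)) droplevels(y) else factor(y)
    if (nlevels(y) < 2) stop_input("classification needs >= 2 classes")
  } else {
    y <- as.numeric(y)
  }
  w <- case_weights %||% rep(1, length(y))
  fitter <- switch(spec$algorithm,
                   decision_tree = .fit_rpart,
                   random_forest = .fit_ranger,
                   xgboost = .fit_xgb,
                   lasso = .fit_glmnet)
  with_seed(spec$seed, fitter(spec, x, y, w))
}

.norm_importance <- function(v, feature_names) {
  out <- stats::setNames(rep(0, length(feature_names)), feature_names)
  v <- v[names(v) %in% feature_names]
  out[names(v)] <- pmax(as.numeric(v), 0)
  s <- sum(out)
  if (s <= 0) rep(1 / length(out), length(out)) else out / s
}

.new_model <- function(spec, fit, x, y, importance, extra = list()) {
  structure(c(list(spec = spec, fit = fit, feature_names = colnames(x),
                   classes = if (is.factor(y)) levels(y) else NULL,
                   importance = importance), extra),
            class = "wpa_model")
}

.fit_rpart <- function(spec, x, y, w) {
  hp <- spec$hyperparams
  df <- data.frame(.y = y, x, check.names = FALSE)
  env <- new.env(parent = environment())
  assign("w", w, envir = env)
  f <- stats::as.formula(".y ~ .", env = env)
  fit <- rpart::rpart(
    f, data = df, weights = w,
    method = if (spec$task == "classification") "class" else "anova",
    control = rpart::rpart.control(
      maxdepth = min(hp$max_depth %||% 30, 30),
      minsplit = hp$minsplit %||% 20,
      cp = hp$cp %||% 0.001, xval = 0)
  )
  imp <- fit$variable.importance
  .new_model(spec, fit, x, y, .norm_importance(imp %||% numeric(0), colnames(x)))
}

.fit_ranger <- function(spec, x, y, w) {
  hp <- spec$hyperparams
  fit <- ranger::ranger(
    x = as.data.frame(x, check.names = FALSE), y = y,
    num.trees = hp$num_trees %||% 300,
    mtry = min(hp$mtry %||% floor(sqrt(ncol(x))), ncol(x)),
    case.weights = w,
    probability = spec$task == "classification",
    importance = "impurity", seed = spec$seed, num.threads = 1
  )
  .new_model(spec, fit, x, y, .norm_importance(ranger::importance(fit), colnames(x)))
}

.fit_xgb <- function(spec, x, y, w) {
  hp <- spec$hyperparams
  if (spec$task == "classification") {
    k <- nlevels(y)
    label <- as.integer(y) - 1L
    params <- if (k == 2) {
      list(objective = "binary:logistic")
    } else {
      list(objective = "multi:softprob", num_class = k)
    }
  } else {
    label <- y
    params <- list(objective = "reg:squarederror")
  }
  params <- c(params, list(max_depth = hp$max_depth %||% 6,
                           eta = hp$eta %||% 0.3,
                           min_child_weight = hp$min_child_weight %||% 1,
                           nthread = 1))
  dtr <- xgboost::xgb.DMatrix(x, label = label, weight = w)
  fit <- xgboost::xgb.train(params = params, data = dtr,
                            nrounds = hp$nrounds %||% 100, verbose = 0)
  it <- tryCatch(xgboost::xgb.importance(model = fit), error = function(e) NULL)
  imp <- if (is.null(it)) numeric(0) else stats::setNames(it$Gain, it$Feature)
  .new_model(spec, fit, x, y, .norm_importance(imp, colnames(x)))
}

.fit_glmnet <- function(spec, x, y, w) {
  hp <- spec$hyperparams
  fam <- if (spec$task == "regression") "gaussian"
         else if (nlevels(y) == 2) "binomial" else "multinomial"
  fit <- glmnet::glmnet(x, y, family = fam, weights = w, alpha = 1)
  s <- hp$lambda %||% ((hp$lambda_frac %||% 0.01) * fit$lambda[1])
  if (s < min(fit$lambda)) {
    # the path can stop early; refit with the requested penalty included
    lamseq <- sort(unique(c(fit$lambda, s)), decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = fam, weights = w, alpha = 1,
                          lambda = lamseq)
  }
  cf <- stats::coef(fit, s = s)
  if (is.list(cf)) {        # multinomial: one coefficient vector per class
    beta <- Reduce(`+`, lapply(cf, function(m) abs(as.numeric(m)[-1])))
  } else {
    beta <- abs(as.numeric(cf)[-1])
  }
  names(beta) <- colnames(x)
  .new_model(spec, fit, x, y, .norm_importance(beta, colnames(x)),
             extra = list(lambda = s))
}

#' Predict from a fitted learner
#'
#' @param object A `"wpa_model"`.
#' @param newdata Feature matrix or data frame holding at least the
#'   training features (reordered to the training order automatically).
#' @param type `"response"` (class labels or numeric predictions),
#'   `"prob"` (class-probability matrix) or `"class"`.
#' @param ... Unused.
#' @return Predictions; probability matrices have one column per class in
#'   training level order.
#' @export
predict.wpa_model <- function(object, newdata,
                              type = c("response", "prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  miss <- setdiff(object$feature_names, colnames(x))
  if (length(miss)) {
    stop_input("newdata missing feature(s): ", paste(miss, collapse = ", "))
  }
  x <- x[, object$feature_names, drop = FALSE]
  if (object$spec$task == "regression") {
    if (type != "response") stop_input("type must be 'response' for regression")
    return(.predict_numeric(object, x))
  }
  prob <- .predict_prob(object, x)
  if (type == "prob") return(prob)
  cls <- object$classes[max.col(prob, ties.method = "first")]
  factor(cls, levels = object$classes)
}

.predict_numeric <- function(object, x) {
  switch(object$spec$algorithm,
    decision_tree = as.numeric(stats::predict(
      object$fit, data.frame(x, check.names = FALSE), type = "vector")),
    random_forest = as.numeric(stats::predict(
      object$fit, data = as.data.frame(x, check.names = FALSE),
      num.threads = 1)$predictions),
    xgboost = as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(x))),
    lasso = as.numeric(stats::predict(object$fit, newx = x, s = object$lambda))
  )
}

.predict_prob <- function(object, x) {
  k <- length(object$classes)
  p <- switch(object$spec$algorithm,
    decision_tree = stats::predict(
      object$fit, data.frame(x, check.names = FALSE), type = "prob"),
    random_forest = stats::predict(
      object$fit, data = as.data.frame(x, check.names = FALSE),
      num.threads = 1)$predictions,
    xgboost = {
      raw <- stats::predict(object$fit, xgboost::xgb.DMatrix(x))
      if (k == 2) cbind(1 - raw, raw) else matrix(raw, ncol = k)
    },
    lasso = {
      raw <- stats::predict(object$fit, newx = x, s = object$lambda,
                            type = "response")
      if (k == 2) cbind(1 - as.numeric(raw), as.numeric(raw))
      else raw[, , 1, drop = TRUE]
    }
  )
  p <- as.matrix(p)
  if (!is.null(colnames(p)) && all(object$classes %in% colnames(p))) {
    p <- p[, object$classes, drop = FALSE]
  }
  colnames(p) <- object$classes
  unname_rows <- p
  rownames(unname_rows) <- NULL
  unname_rows
}

#' @export
print.wpa_model <- function(x, ...) {
  cat(sprintf("<wpa_model> %s (%s), %d features\n",
              x$spec$algorithm, x$spec$task, length(x$feature_names)))
  if (!is.null(x$classes)) {
    cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  }
  top <- sort(x$importance, decreasing = TRUE)[1:min(5, length(x$importance))]
  cat("  top features:",
      paste(sprintf("%s (%.2f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Default hyperparameter search grids
#'
#' Small conventional grids per learner family, tuned in the inner loop of
#' the nested cross-validation: tree depth for CART; number of trees and
#' features per split for the forest; depth, learning rate and boosting
#' rounds for gradient boosting; a logarithmic penalty grid (as fractions
#' of the data-derived maximal penalty) for the lasso.
#'
#' @return Named list (by algorithm) of lists of hyperparameter settings.
#' @export
default_grids <- function() {
  xg <- expand.grid(max_depth = c(3, 6), eta = c(0.1, 0.3),
                    nrounds = c(100, 300))
  rf <- expand.grid(num_trees = c(100, 300), mtry = c(7, 16))
  list(
    decision_tree = lapply(c(3, 5, 10, 30), function(d) list(max_depth = d)),
    random_forest = lapply(seq_len(nrow(rf)), function(i) as.list(rf[i, ])),
    xgboost = lapply(seq_len(nrow(xg)), function(i) as.list(xg[i, ])),
    lasso = lapply(10^seq(0, -4, length.out = 50),
                   function(f) list(lambda_frac = f))
  )
}

#' Reduced single-setting grids
#'
#' One fixed setting per learner family; with a single candidate the inner
#' tuning loop is skipped, which keeps full experiment-grid runs desk-scale
#' while preserving the outer-fold error estimation.
#'
#' @return Named list (by algorithm) of single-element grids.
#' @export
reduced_grids <- function() {
  list(
    decision_tree = list(list(max_depth = 5)),
    random_forest = list(list(num_trees = 100, mtry = 7)),
    xgboost = list(list(max_depth = 3, eta = 0.3, nrounds = 50)),
    lasso = list(list(lambda_frac = 0.01))
  )
}
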