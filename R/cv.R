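#' Randomly assign participants to folds
#'
#' Uniform, size-balanced (sizes differ by at most one) and seeded. Folding
#' is always by participant, never by window, so that no individual
#' contributes to both sides of any split.
#'
#' @param participant_ids Participant identifiers (duplicates collapsed).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Named integer vector mapping participant id to fold index
#'   `0..k-1`, with attributes `k` and `seed`.
#' @export
assign_folds <- function(participant_ids, k = 5, seed = 1L) {
  ids <- unique(as.character(participant_ids))
  if (length(ids) < k) {
    stop_input("need at least ", k, " participants for ", k, " folds")
  }
  with_seed(seed, {
    shuffled <- sample(ids)
    fold <- stats::setNames(rep_len(seq_len(k) - 1L, length(ids)), shuffled)
    fold <- fold[ids]
    attr(fold, "k") <- k
    attr(fold, "seed") <- as.integer(seed)
    fold
  })
}

# selection metric on held-out predictions; larger is better
.selection_score <- function(task, truth, pred, positive) {
  if (task == "regression") return(-rmse(pred, truth))
  lev <- levels(truth)
  cm <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  if (length(lev) == 2) {
    i <- match(positive, lev)
    f1_score(tp = cm[i, i], fp = sum(cm[-i, i]), fn = sum(cm[i, -i]))
  } else {
    f1 <- .per_class_f1(cm)
    present <- rowSums(cm) > 0
    mean(f1[present])
  }
}

.hp_label <- function(hp) {
  if (length(hp) == 0) return("(defaults)")
  paste(names(hp), unlist(hp), sep = "=", collapse = ", ")
}

#' Participant-grouped nested cross-validation
#'
#' Outer loop: participants are randomly split into `k` size-balanced
#' folds; each fold in turn is held out for error estimation. Inner loop:
#' the outer-training participants are split into `k - 1` folds and every
#' hyperparameter setting in `grid` is scored on them (positive-class F1
#' for binary tasks, macro F1 for multi-class, negative RMSE for
#' regression); the best setting is refit on the full outer-training set —
#' with inverse-frequency class weights recomputed on it — and evaluated on
#' the held-out fold. With a single-setting grid the inner loop is skipped.
#' A participant-disjointness assertion guards every outer split.
#'
#' @param dataset A [build_task_dataset()] result.
#' @param algorithm Learner family, see [learner_spec()].
#' @param grid List of hyperparameter settings; defaults to
#'   `default_grids()[[algorithm]]`.
#' @param k Number of outer folds (inner loop uses `k - 1`).
#' @param seed Integer seed for fold assignment and fitting.
#' @return An object of class `"wpa_cv"`: per-fold metrics (`folds`),
#'   metric means and SDs (`summary`), the confusion matrix summed over
#'   outer folds, the mean normalized feature importance, per-class F1 by
#'   fold, the best setting by mean inner score, and a `final_model` refit
#'   on all data with that setting.
#' @export
nested_cv <- function(dataset, algorithm, grid = NULL, k = 5, seed = 1L) {
  stopifnot(inherits(dataset, "wpa_task"))
  grid <- grid %||% default_grids()[[algorithm]]
  task <- if (dataset$kind == "ee_regression") "regression" else "classification"
  groups <- as.character(dataset$groups)
  folds <- assign_folds(groups, k, seed)
  lev <- if (task == "classification") levels(dataset$y) else NULL
  is_binary <- task == "classification" && length(lev) == 2

  fit_weighted <- function(hp, idx, fold_seed) {
    spec <- learner_spec(algorithm, task, hyperparams = hp, seed = fold_seed)
    w <- if (task == "classification") {
      cw <- compute_class_weights(dataset$y[idx])
      as.numeric(cw[as.character(dataset$y[idx])])
    } else NULL
    wpa_fit(spec, dataset$x[idx, , drop = FALSE], dataset$y[idx], w)
  }

  fold_rows <- list()
  confusion <- NULL
  imp <- matrix(0, ncol(dataset$x), k, dimnames = list(colnames(dataset$x), NULL))
  pcf1 <- if (task == "classification") {
    matrix(NA_real_, length(lev), k, dimnames = list(lev, NULL))
  } else NULL
  inner_scores <- matrix(NA_real_, length(grid), k)
  chosen_list <- vector("list", k)

  for (i in seq_len(k) - 1L) {
    test_parts <- names(folds)[folds == i]
    train_parts <- setdiff(names(folds), test_parts)
    # leakage guard: asserted on every run
    if (length(intersect(train_parts, test_parts)) > 0) {
      stop("internal error: participant appears in both training and test")
    }
    test_idx <- which(groups %in% test_parts)
    train_idx <- which(groups %in% train_parts)
    fold_seed <- seed + 37L * (i + 1L)

    if (length(grid) > 1) {
      inner <- assign_folds(train_parts, k - 1, fold_seed)
      for (g in seq_along(grid)) {
        sc <- numeric(0)
        for (j in seq_len(k - 1) - 1L) {
          val_parts <- names(inner)[inner == j]
          fit_parts <- setdiff(train_parts, val_parts)
          fit_idx <- which(groups %in% fit_parts)
          val_idx <- which(groups %in% val_parts)
          s <- tryCatch({
            m <- fit_weighted(grid[[g]], fit_idx, fold_seed)
            pred <- predict(m, dataset$x[val_idx, , drop = FALSE])
            .selection_score(task, dataset$y[val_idx], pred, dataset$positive)
          }, error = function(e) NA_real_)
          sc <- c(sc, s)
        }
        inner_scores[g, i + 1] <- mean(sc, na.rm = TRUE)
      }
      best_g <- which.max(inner_scores[, i + 1])
    } else {
      best_g <- 1L
      inner_scores[1, i + 1] <- NA_real_
    }
    chosen <- grid[[best_g]]
    chosen_list[[i + 1]] <- chosen

    model <- fit_weighted(chosen, train_idx, fold_seed)
    imp[, i + 1] <- model$importance[rownames(imp)]

    if (task == "regression") {
      pred <- predict(model, dataset$x[test_idx, , drop = FALSE])
      fold_rows[[i + 1]] <- data.frame(
        fold = i, hyperparams = .hp_label(chosen),
        rmse = rmse(pred, dataset$y[test_idx]), stringsAsFactors = FALSE)
    } else {
      truth <- dataset$y[test_idx]
      prob <- predict(model, dataset$x[test_idx, , drop = FALSE], type = "prob")
      pred <- factor(lev[max.col(prob, ties.method = "first")], levels = lev)
      cm <- table(truth = factor(truth, levels = lev),
                  predicted = factor(pred, levels = lev))
      confusion <- if (is.null(confusion)) cm else confusion + cm
      f1c <- .per_class_f1(cm)
      f1c[rowSums(cm) == 0] <- NA_real_   # class absent from this test fold
      pcf1[, i + 1] <- f1c
      acc <- sum(diag(cm)) / sum(cm)
      if (is_binary) {
        p <- match(dataset$positive, lev)
        both <- all(rowSums(cm) > 0)
        if (!both) {
          warning("a class is absent from outer test fold ", i,
                  "; AUC and balanced accuracy recorded as NA", call. = FALSE)
        }
        fold_rows[[i + 1]] <- data.frame(
          fold = i, hyperparams = .hp_label(chosen),
          f1 = f1c[p],
          auc = if (both) auc(prob[, p], truth == lev[p]) else NA_real_,
          balanced_accuracy = if (both) {
            balanced_accuracy(tp = cm[p, p], fp = sum(cm[-p, p]),
                              tn = sum(cm[-p, -p]), fn = sum(cm[p, -p]))
          } else NA_real_,
          accuracy = acc, stringsAsFactors = FALSE)
      } else {
        present <- rowSums(cm) > 0
        fold_rows[[i + 1]] <- data.frame(
          fold = i, hyperparams = .hp_label(chosen),
          f1 = mean(f1c[present]),
          auc = NA_real_,
          balanced_accuracy = mean(diag(cm)[present] / rowSums(cm)[present]),
          accuracy = acc, stringsAsFactors = FALSE)
      }
    }
  }

  folds_df <- do.call(rbind, fold_rows)
  metric_cols <- setdiff(names(folds_df), c("fold", "hyperparams"))
  metric_cols <- metric_cols[vapply(metric_cols, function(m) {
    any(!is.na(folds_df[[m]]))   # drop metrics undefined in every fold
  }, logical(1))]
  summ <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(folds_df[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(folds_df[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  mean_imp <- rowMeans(imp)
  mean_imp <- mean_imp / sum(mean_imp)

  best_overall <- if (length(grid) > 1) {
    grid[[which.max(rowMeans(inner_scores, na.rm = TRUE))]]
  } else {
    grid[[1]]
  }
  final_model <- fit_weighted(best_overall, seq_along(groups), seed)

  structure(
    list(task = task, kind = dataset$kind, target = dataset$target,
         stratum = dataset$stratum, algorithm = algorithm, k = k,
         seed = as.integer(seed), n_windows = nrow(dataset$x),
         n_participants = length(unique(groups)),
         folds = folds_df, summary = summ, confusion = confusion,
         importance = mean_imp, per_class_f1 = pcf1,
         chosen = chosen_list, best_params = best_overall,
         final_model = final_model),
    class = "wpa_cv"
  )
}

#' @export
print.wpa_cv <- function(x, ...) {
  cat(sprintf("<wpa_cv> %s%s | %s | stratum %s | %d-fold nested CV\n",
              x$kind, if (!is.null(x$target)) paste0(" [", x$target, "]") else "",
              x$algorithm, x$stratum, x$k))
  cat(sprintf("  %d windows, %d participants\n", x$n_windows, x$n_participants))
  for (r in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-18s %.3f (%.3f)\n", x$summary$metric[r],
                x$summary$mean[r], x$summary$sd[r]))
  }
  invisible(x)
}

#' @export
summary.wpa_cv <- function(object, ...) object$summary

#' Top-ranked features by mean importance
#'
#' Feature importance averaged over the outer folds, rescaled to sum to
#' one, ranked; ties break by canonical feature order.
#'
#' @param result A [nested_cv()] result.
#' @param n Number of features to return.
#' @return Data frame with columns `feature` and `score`.
#' @export
top_features <- function(result, n = 15) {
  stopifnot(inherits(result, "wpa_cv"))
  imp <- result$importance
  if (n > length(imp)) stop_input("n exceeds the number of features")
  ord <- order(-imp)    # stable: ties keep canonical order
  data.frame(feature = names(imp)[ord][seq_len(n)],
             score = as.numeric(imp[ord][seq_len(n)]),
             stringsAsFactors = FALSE)
}
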