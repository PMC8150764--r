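#' Enumerate the experiment grid
#'
#' The full modelling grid: three one-vs-rest activity-type targets and
#' three intensity targets, each crossed with the four learner families and
#' the four age strata (48 + 48 models); energy-expenditure regression per
#' learner and stratum (16 models); and individual-activity recognition
#' with the gradient-boosting learner per stratum (4 models) — 116 model
#' instances in total. The `"all"` stratum pools the three age groups.
#'
#' @param algorithms Learner families to include.
#' @param strata Age strata to include.
#' @return Data frame with columns `task`, `target`, `algorithm`,
#'   `stratum`, one row per model instance.
#' @export
experiment_grid <- function(algorithms = c("decision_tree", "random_forest",
                                           "xgboost", "lasso"),
                            strata = c("young", "middle", "old", "all")) {
  rows <- list()
  add <- function(task, target, algorithm, stratum) {
    rows[[length(rows) + 1]] <<- data.frame(
      task = task, target = target, algorithm = algorithm, stratum = stratum,
      stringsAsFactors = FALSE)
  }
  for (s in strata) {
    for (a in algorithms) {
      for (tg in c("sedentary", "locomotion", "lifestyle")) {
        add("type_binary", tg, a, s)
      }
      for (tg in c("low", "light", "moderate")) {
        add("intensity_binary", tg, a, s)
      }
      add("ee_regression", NA_character_, a, s)
    }
    if ("xgboost" %in% algorithms) {
      add("individual_multiclass", NA_character_, "xgboost", s)
    }
  }
  do.call(rbind, rows)
}

#' Run the full experiment grid
#'
#' Builds the task dataset and runs participant-grouped nested
#' cross-validation for every cell of the grid. Cells whose dataset cannot
#' be formed (an empty stratum, say) are recorded as skipped with a
#' warning rather than aborting the run.
#'
#' @param windows Feature table from [extract_feature_table()].
#' @param roster Exclusion-filtered roster.
#' @param grid Grid enumeration from [experiment_grid()].
#' @param grids Hyperparameter grids per algorithm; [reduced_grids()] by
#'   default so a full run stays desk-scale.
#' @param k Outer folds.
#' @param seed Integer seed; cell seeds are derived from it.
#' @param mapping,scheme Activity-type mapping and intensity cutoffs.
#' @param verbose Print per-cell progress.
#' @return An object of class `"wpa_experiment"`: `manifest` (one row per
#'   model instance with its summary metrics), `results` (list of
#'   `"wpa_cv"` objects, NULL where skipped), plus the grid and seed.
#' @export
run_experiment_grid <- function(windows, roster, grid = experiment_grid(),
                                grids = reduced_grids(), k = 5, seed = 1L,
                                mapping = default_type_mapping(),
                                scheme = intensity_scheme(),
                                verbose = FALSE) {
  results <- vector("list", nrow(grid))
  man <- grid
  man$status <- "ok"
  man$seed <- seed + seq_len(nrow(grid))
  man$n_windows <- NA_integer_
  man$metric <- ifelse(grid$task == "ee_regression", "rmse", "f1")
  man$mean <- NA_real_
  man$sd <- NA_real_
  for (r in seq_len(nrow(grid))) {
    cell <- grid[r, ]
    if (verbose) {
      message(sprintf("[%d/%d] %s %s %s %s", r, nrow(grid), cell$task,
                      ifelse(is.na(cell$target), "", cell$target),
                      cell$algorithm, cell$stratum))
    }
    res <- tryCatch({
      ds <- build_task_dataset(
        windows, roster, kind = cell$task,
        target = if (is.na(cell$target)) NULL else cell$target,
        stratum = cell$stratum, mapping = mapping, scheme = scheme)
      nested_cv(ds, cell$algorithm, grid = grids[[cell$algorithm]],
                k = k, seed = man$seed[r])
    }, error = function(e) {
      warning(sprintf("skipped %s/%s/%s/%s: %s", cell$task, cell$target,
                      cell$algorithm, cell$stratum, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    results[[r]] <- res
    if (is.null(res)) {
      man$status[r] <- "skipped"
    } else {
      man$n_windows[r] <- res$n_windows
      m <- res$summary
      row <- m[m$metric == man$metric[r], ]
      man$mean[r] <- row$mean
      man$sd[r] <- row$sd
    }
  }
  structure(list(manifest = man, results = results, grid = grid,
                 seed = as.integer(seed), k = k),
            class = "wpa_experiment")
}

#' @export
print.wpa_experiment <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<wpa_experiment> %d model instances (%d ok, %d skipped), k = %d\n",
              nrow(m), sum(m$status == "ok"), sum(m$status == "skipped"), x$k))
  print(stats::aggregate(mean ~ task + metric, data = m, FUN = mean))
  invisible(x)
}

.fmt_mean_sd <- function(mean, sd) {
  ifelse(is.na(mean), "", sprintf("%.3f (%.3f)", mean, sd))
}

# wide mean (sd) table with one row per `rowvar` value, one column per stratum
.wide_table <- function(man, task, rowvar = "target") {
  m <- man[man$task == task & man$status == "ok", , drop = FALSE]
  if (nrow(m) == 0) return(NULL)
  strata <- unique(man$stratum)
  rows <- unique(m[[rowvar]])
  out <- data.frame(row = rows, stringsAsFactors = FALSE)
  names(out) <- rowvar
  for (s in strata) {
    out[[s]] <- vapply(rows, function(rv) {
      sel <- m[[rowvar]] == rv & m$stratum == s
      if (!any(sel)) return("")
      .fmt_mean_sd(m$mean[sel][1], m$sd[sel][1])
    }, character(1))
  }
  out
}

#' Report tables for an experiment run
#'
#' Produces the standard report shapes: per-target activity-type and
#' intensity F1 tables by algorithm and stratum, the energy-expenditure
#' RMSE table, the per-activity F1 table of the multi-class model with a
#' macro-average row, the top-15 feature importances per
#' gradient-boosting model, and the summed confusion matrices. Every cell
#' is the mean (SD) over the outer cross-validation folds.
#'
#' @param experiment A [run_experiment_grid()] result.
#' @param n_top Number of top features to tabulate.
#' @return Named list of data frames / matrices.
#' @export
report_tables <- function(experiment, n_top = 15) {
  stopifnot(inherits(experiment, "wpa_experiment"))
  man <- experiment$manifest
  res <- experiment$results

  by_algo <- function(task) {
    algos <- unique(man$algorithm[man$task == task])
    out <- list()
    for (a in algos) {
      tab <- .wide_table(man[man$algorithm == a, , drop = FALSE], task)
      if (!is.null(tab)) {
        tab <- cbind(algorithm = a, tab, stringsAsFactors = FALSE)
        out[[a]] <- tab
      }
    }
    if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE))) else NULL
  }

  # individual-activity table: per-class F1 mean (sd) per stratum + macro row
  idx_multi <- which(man$task == "individual_multiclass" & man$status == "ok")
  individual <- NULL
  if (length(idx_multi)) {
    acts <- rownames(res[[idx_multi[1]]]$per_class_f1)
    individual <- data.frame(activity = c(acts, "Macro average (F1 score)"),
                             stringsAsFactors = FALSE)
    for (r in idx_multi) {
      cv <- res[[r]]
      pc <- cv$per_class_f1
      mu <- apply(pc, 1, mean, na.rm = TRUE)
      sdv <- apply(pc, 1, stats::sd, na.rm = TRUE)
      macro_mu <- macro_f1(mu)
      macro_per_fold <- apply(pc, 2, function(v) mean(v, na.rm = TRUE))
      individual[[man$stratum[r]]] <- c(
        .fmt_mean_sd(mu, sdv),
        .fmt_mean_sd(mean(macro_per_fold), stats::sd(macro_per_fold)))
    }
  }

  topf <- list()
  confusions <- list()
  for (r in which(man$status == "ok")) {
    key <- paste(man$task[r], man$target[r], man$algorithm[r],
                 man$stratum[r], sep = "/")
    if (man$algorithm[r] == "xgboost") {
      topf[[key]] <- top_features(res[[r]], n_top)
    }
    if (!is.null(res[[r]]$confusion)) confusions[[key]] <- res[[r]]$confusion
  }

  list(type_f1 = by_algo("type_binary"),
       intensity_f1 = by_algo("intensity_binary"),
       ee_rmse = .wide_table(man, "ee_regression", rowvar = "algorithm"),
       individual_f1 = individual,
       top_features = topf,
       confusion_matrices = confusions)
}

#' Write report tables to CSV files
#'
#' @param tables Output of [report_tables()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("type_f1", "intensity_f1", "ee_rmse", "individual_f1")) {
    if (!is.null(tables[[nm]])) {
      utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  for (key in names(tables$top_features)) {
    f <- file.path(dir, paste0("top_features_", gsub("[^A-Za-z0-9]+", "_", key),
                               ".csv"))
    utils::write.csv(tables$top_features[[key]], f, row.names = FALSE)
  }
  for (key in names(tables$confusion_matrices)) {
    f <- file.path(dir, paste0("confusion_", gsub("[^A-Za-z0-9]+", "_", key),
                               ".csv"))
    utils::write.csv(as.data.frame.matrix(tables$confusion_matrices[[key]]), f)
  }
  invisible(dir)
}
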