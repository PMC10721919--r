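# Permutation feature importance: on the best-balanced-accuracy split of an
# evaluation, each feature of the held-out test rows is shuffled repeatedly
# and the drop in balanced accuracy recorded.

# low-level core: permute each test column of a fitted model
permutation_importance_fit <- function(fit, x_test, y_test,
                                       n_permutations = 30L, seed = 1) {
  base <- balanced_accuracy(y_test, predict(fit, x_test))
  feats <- fit$features
  rows <- vector("list", length(feats))
  for (j in seq_along(feats)) {
    drops <- numeric(n_permutations)
    for (k in seq_len(n_permutations)) {
      xp <- x_test
      xp[[feats[j]]] <- with_seed(derive_seed(seed, j * 1009L + k),
                                  sample(xp[[feats[j]]]))
      drops[k] <- base - balanced_accuracy(y_test, predict(fit, xp))
    }
    rows[[j]] <- tibble::tibble(feature = feats[j],
                                mean_drop = mean(drops), sd_drop = sd(drops))
  }
  list(base_accuracy = base, importances = dplyr::bind_rows(rows))
}

#' Permutation feature importance
#'
#' Evaluates the task (or reuses a supplied [evaluate_task()] result), refits
#' the model on the training rows of the first split achieving the maximum
#' balanced accuracy, and permutes each feature of that split's test rows
#' `n_permutations` times, recording the mean and sd of the balanced-accuracy
#' drop. Drops may be negative for irrelevant features. Family-level relative
#' importances are the positive-part mean drops aggregated by feature family
#' and normalised to sum to 1.
#'
#' @inheritParams evaluate_task
#' @param n_permutations independent shuffles per feature (30 by default).
#' @param eval optional precomputed `papilla_eval` for the same table/task.
#' @return A `papilla_importance`: `importances` tibble (feature, family,
#'   mean_drop, sd_drop, rank), `family_importance` tibble, `base_accuracy`
#'   of the best split, and the evaluation settings.
#' @export
permutation_importance <- function(table, task = c("type", "gender", "age",
                                                   "participant"),
                                   family = "all", model = "svm",
                                   scheme = "random", n_splits = 50L,
                                   n_permutations = 30L, seed = 1,
                                   eval = NULL) {
  task <- match.arg(task)
  if (is.null(eval)) {
    eval <- evaluate_task(table, task = task, family = family, model = model,
                          scheme = scheme, n_splits = n_splits, seed = seed)
  }
  keep <- stats::complete.cases(table[, c(eval$label_column,
                                          eval$feature_columns)])
  tab <- table[keep, , drop = FALSE]
  y <- factor(tab[[eval$label_column]])
  x <- tab[, eval$feature_columns, drop = FALSE]

  best <- which.max(eval$scores$balanced_accuracy)  # first max under seed order
  te <- eval$test_sets[[best]]
  tr <- setdiff(seq_along(y), te)
  fit <- fit_classifier(x[tr, , drop = FALSE], y[tr], model = eval$model,
                        standardize = eval$standardize)
  core <- permutation_importance_fit(fit, x[te, , drop = FALSE], y[te],
                                     n_permutations = n_permutations,
                                     seed = derive_seed(seed, 777L))

  imp <- core$importances |>
    dplyr::left_join(feature_families(), by = "feature") |>
    dplyr::arrange(dplyr::desc(.data$mean_drop)) |>
    dplyr::mutate(rank = dplyr::row_number())
  fam <- imp |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(mean_drop = mean(.data$mean_drop), .groups = "drop") |>
    dplyr::mutate(positive = pmax(.data$mean_drop, 0),
                  relative_importance = if (sum(.data$positive) > 0) {
                    .data$positive / sum(.data$positive)
                  } else rep(1 / dplyr::n(), dplyr::n())) |>
    dplyr::select("family", "mean_drop", "relative_importance")

  structure(list(task = task, model = eval$model, scheme = eval$scheme,
                 best_split = best, base_accuracy = core$base_accuracy,
                 n_permutations = n_permutations,
                 importances = imp, family_importance = fam),
            class = "papilla_importance")
}

#' @export
print.papilla_importance <- function(x, ...) {
  cat(sprintf("<papilla_importance> task %s | %s | best-split accuracy %.3f | %d permutations\n",
              x$task, toupper(x$model), x$base_accuracy, x$n_permutations))
  print(utils::head(x$importances, 5L))
  invisible(x)
}
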