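# broom-style tidiers for fitted result objects.

#' Tidy per-split scores of an evaluation
#'
#' @param x a `papilla_eval`.
#' @param ... unused.
#' @return Tibble with one row per split: task, family, model, scheme,
#'   split, balanced_accuracy, n_test.
#' @export
tidy.papilla_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(task = x$task, family = x$family, model = x$model,
                   scheme = x$scheme),
    x$scores)
}

#' One-row summary of an evaluation
#'
#' @param x a `papilla_eval`.
#' @param ... unused.
#' @return One-row tibble: task, family, model, scheme, mean and sd of
#'   balanced accuracy, number of splits, number of segments.
#' @export
glance.papilla_eval <- function(x, ...) {
  tibble::tibble(task = x$task, family = x$family, model = x$model,
                 scheme = x$scheme, balanced_accuracy = x$mean,
                 sd = x$sd, n_splits = nrow(x$scores), n = x$n)
}

#' Tidy permutation importances
#'
#' @param x a `papilla_importance`.
#' @param ... unused.
#' @return Tibble with one row per feature: feature, family, mean_drop,
#'   sd_drop, rank.
#' @export
tidy.papilla_importance <- function(x, ...) {
  dplyr::select(x$importances, "feature", "family", "mean_drop", "sd_drop",
                "rank")
}

#' One-row summary of a permutation-importance report
#'
#' @param x a `papilla_importance`.
#' @param ... unused.
#' @return One-row tibble: task, model, best_split, base_accuracy,
#'   n_permutations, top_feature.
#' @export
glance.papilla_importance <- function(x, ...) {
  tibble::tibble(task = x$task, model = x$model, best_split = x$best_split,
                 base_accuracy = x$base_accuracy,
                 n_permutations = x$n_permutations,
                 top_feature = x$importances$feature[1L])
}

#' Tidy a papillae map
#'
#' @param x a `papillae_map`.
#' @param ... unused.
#' @return The detection tibble with the surface id attached.
#' @export
tidy.papillae_map <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(surface_id = x$surface_id), x$detections)
}
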