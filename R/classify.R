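# Whole-surface papillae mapping ("tongue prints"): train a papilla-type
# classifier on a labelled feature table, sweep a new surface, classify every
# candidate segment and keep the detections typed fungiform/filiform.

#' Train a papilla-type classifier
#'
#' Optionally prunes correlated features ([prune_correlated()]), then fits the
#' model on all rows of the table against the `type` label. The trained object
#' stores the feature schema and scaling so it can be applied to features
#' assembled from new surfaces.
#'
#' @param table labelled feature table from [assemble_features()].
#' @param model `"svm"` or `"lr"`.
#' @param prune_threshold correlation-pruning threshold, or `NULL` to keep all
#'   features.
#' @param standardize z-score features before fitting.
#' @return A `papilla_classifier`.
#' @export
train_type_classifier <- function(table, model = c("svm", "lr"),
                                  prune_threshold = 0.65,
                                  standardize = TRUE) {
  model <- match.arg(model)
  removal_log <- NULL
  if (!is.null(prune_threshold)) {
    table <- prune_correlated(table, prune_threshold)
    removal_log <- attr(table, "removal_log")
  }
  feats <- family_columns(table, "all")
  keep <- stats::complete.cases(table[, c("type", feats)])
  tab <- table[keep, , drop = FALSE]
  fit <- fit_classifier(tab[, feats, drop = FALSE], tab$type, model = model,
                        standardize = standardize)
  structure(list(fit = fit, features = feats, model = model,
                 prune_threshold = prune_threshold,
                 removal_log = removal_log,
                 classes = fit$levels, n_train = nrow(tab)),
            class = "papilla_classifier")
}

#' @export
print.papilla_classifier <- function(x, ...) {
  cat(sprintf("<papilla_classifier> %s on %d features, %d training segments; classes: %s\n",
              toupper(x$model), length(x$features), x$n_train,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @export
predict.papilla_classifier <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0L) {
    stop("schema error: feature columns missing from new data: ",
         paste(missing, collapse = ", "))
  }
  predict_confidence(object$fit, newdata)
}

#' Map the papillae of a surface
#'
#' Sweeps the surface for candidate segments ([sweep_surface()]), assembles
#' their features and classifies each with a trained type classifier.
#' Detections predicted `"none"` are excluded from the map. Deterministic
#' given `seed`.
#'
#' @param surface a [tri_mesh()] or `annotated_surface`.
#' @param classifier a [train_type_classifier()] result.
#' @param r,delta,stop_after,max_iterations sweep parameters
#'   (see [sweep_surface()]).
#' @param topo_subsample subsample size for the topological features.
#' @param max_filtration Rips filtration cap (um) for the topological
#'   features; the default keeps exact H1 tractable at
#'   `topo_subsample = 1000`. Use the same value the classifier's training
#'   features were assembled with. `NULL` uses each cloud's enclosing radius.
#' @param ransac a [ransac_params()].
#' @param seed integer seed.
#' @param surface_id identifier stored in the map.
#' @return A `papillae_map`: tibble of detections (M coordinates, predicted
#'   type, classifier confidence) plus counts by type.
#' @export
map_papillae <- function(surface, classifier, r = segment_radius(),
                         delta = 100, stop_after = 100L,
                         max_iterations = 5000L, topo_subsample = 1000L,
                         max_filtration = 100,
                         ransac = ransac_params(), seed = 1,
                         surface_id = "surface") {
  mesh <- if (inherits(surface, "annotated_surface")) surface$mesh else surface
  if (!inherits(mesh, "tri_mesh")) stop("surface must be a tri_mesh or annotated_surface")

  segments <- sweep_surface(mesh, r = r, delta = delta,
                            stop_after = stop_after,
                            max_iterations = max_iterations,
                            ransac = ransac, seed = seed)
  if (length(segments) == 0L) {
    return(empty_map(surface_id, classifier$classes))
  }
  feats <- suppressWarnings(
    assemble_features(segments, topo_subsample = topo_subsample,
                      max_filtration = max_filtration,
                      ransac = ransac, seed = derive_seed(seed, 13L)))
  pred <- predict(classifier, feats)
  m_pts <- t(vapply(segments[feats$segment], `[[`, numeric(3), "M"))
  det <- tibble::tibble(
    x = m_pts[, 1], y = m_pts[, 2], z = m_pts[, 3],
    type = pred$class, confidence = pred$confidence) |>
    dplyr::filter(.data$type != "none")
  structure(list(surface_id = surface_id, detections = det,
                 counts = table(factor(det$type,
                                       levels = setdiff(classifier$classes,
                                                        "none"))),
                 n_segments = length(segments), r = r, seed = seed),
            class = "papillae_map")
}

empty_map <- function(surface_id, classes) {
  structure(list(surface_id = surface_id,
                 detections = tibble::tibble(
                   x = numeric(), y = numeric(), z = numeric(),
                   type = character(), confidence = numeric()),
                 counts = table(factor(character(),
                                       levels = setdiff(classes, "none"))),
                 n_segments = 0L, r = NA_real_, seed = NA_integer_),
            class = "papillae_map")
}

#' @export
print.papillae_map <- function(x, ...) {
  cat(sprintf("<papillae_map> %s: %d detections from %d candidate segments\n",
              x$surface_id, nrow(x$detections), x$n_segments))
  for (cl in names(x$counts)) cat(sprintf("  %s: %d\n", cl, x$counts[[cl]]))
  invisible(x)
}
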