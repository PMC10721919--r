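# Feature-table assembly: one tidy row per segment, joining baseline,
# curvature and topological feature families with the segment's labels.

#' Canonical feature columns and their families
#'
#' @return Tibble with columns `feature` and `family`
#'   (`baseline`, `curvature`, `topological`), in the canonical column order.
#' @export
feature_families <- function() {
  tibble::tibble(
    feature = c("height_um", "radius_um",
                "gauss_max", "gauss_min", "mean_max", "mean_min",
                "k_ratio", "k_positiveratio",
                "short_bars_h0", "short_bars_h1", "entropy_h0", "entropy_h1",
                "amp_landscape_h0", "amp_landscape_h1",
                "amp_image_h0", "amp_image_h1",
                "amp_wasserstein_h0", "amp_wasserstein_h1",
                "amp_bottleneck_h0", "amp_bottleneck_h1"),
    family = c(rep("baseline", 2L), rep("curvature", 6L),
               rep("topological", 12L)))
}

#' Assemble the per-segment feature table
#'
#' Runs [geometry_features()] and [topo_features()] on every segment and joins
#' the results with the segment labels (type, participant, gender, age group)
#' into one tidy tibble, in the canonical column order. Segments whose feature
#' computation fails are dropped with a warning. Deterministic given `seed`.
#'
#' @param segments list of labelled `papilla_segment`s.
#' @param topo_subsample point-cloud subsample size for the topological
#'   features (1000 by default; smaller values trade fidelity for speed).
#' @param ransac a [ransac_params()] for the baseline height.
#' @param seed integer seed.
#' @inheritParams topo_features
#' @return A tibble with label columns (`type`, `participant`, `gender`,
#'   `age`, `age_group`) followed by the [feature_families()] columns.
#' @export
assemble_features <- function(segments, topo_subsample = 1000L,
                              ransac = ransac_params(), seed = 1,
                              max_filtration = NULL, grid_size = 1000L,
                              image_resolution = 100L,
                              image_bandwidth = NULL) {
  rows <- purrr::imap(segments, function(seg, i) {
    tryCatch({
      geo <- geometry_features(seg, ransac = ransac,
                               seed = derive_seed(seed, 2L * i))
      topo <- topo_features(seg$patch$vertices, n = topo_subsample,
                            seed = derive_seed(seed, 2L * i + 1L),
                            max_filtration = max_filtration,
                            grid_size = grid_size,
                            image_resolution = image_resolution,
                            image_bandwidth = image_bandwidth)
      meta <- seg$metadata
      dplyr::bind_cols(
        tibble::tibble(
          segment = i,
          type = seg$label,
          participant = meta$participant %||% NA_character_,
          gender = meta$gender %||% NA_character_,
          age = meta$age %||% NA_real_,
          age_group = meta$age_group %||% NA_character_),
        geo, topo)
    }, error = function(e) {
      warning("segment ", i, " dropped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) stop("no segment yielded a complete feature row")
  out
}

#' Greedy correlation pruning of feature columns
#'
#' Walks the feature columns in canonical order and removes each column whose
#' absolute Pearson correlation with any already-kept column exceeds
#' `threshold` (so of a correlated pair, the later column in canonical order
#' is dropped). The removal log records each decision.
#'
#' @param table a feature table from [assemble_features()].
#' @param threshold absolute correlation above which a column is removed
#'   (0.65 by default).
#' @return The table without the removed columns; the removal log (tibble
#'   `removed`, `kept_with`, `correlation`) is attached as attribute
#'   `removal_log`.
#' @export
prune_correlated <- function(table, threshold = 0.65) {
  feats <- intersect(feature_families()$feature, names(table))
  if (length(feats) < 2L) stop("need at least 2 feature columns")
  x <- as.matrix(table[, feats])
  cm <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  kept <- feats[1L]
  removed <- character(0)
  log <- list()
  for (f in feats[-1L]) {
    r <- cm[f, kept]
    worst <- which.max(abs(r))
    if (abs(r[worst]) > threshold) {
      removed <- c(removed, f)
      log[[length(log) + 1L]] <- tibble::tibble(
        removed = f, kept_with = kept[worst], correlation = r[worst])
    } else {
      kept <- c(kept, f)
    }
  }
  out <- table[, setdiff(names(table), removed)]
  attr(out, "removal_log") <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(removed = character(), kept_with = character(),
                   correlation = numeric())
  out
}
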