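# One-command synthetic analogue of the full study: generate a cohort, sweep
# every surface, assemble and prune features, run the four classification
# tasks across feature families, models and split schemes, compute permutation
# importance, and map one surface.

#' Study configuration
#'
#' Collects every knob of [run_study()] into one (JSON-serialisable) object.
#'
#' @param n_participants,segments_per_participant cohort size.
#' @param effects a [cohort_effects()].
#' @param noise_sd,mesh_pitch surface generation parameters (um).
#' @param r,delta segment sweep radii (um).
#' @param topo_subsample point subsample for topological features.
#' @param topo_max_filtration Rips filtration cap (um) for the topological
#'   features; keeps exact H1 tractable at `topo_subsample = 1000` (bars
#'   alive at the cap are censored). `NULL` uses each cloud's enclosing
#'   radius.
#' @param tasks,families,models,schemes which evaluations to run.
#' @param n_splits random splits per evaluation.
#' @param prune_threshold correlation-pruning threshold.
#' @param n_permutations shuffles per feature for importance.
#' @param importance_task task whose importances are reported.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_participants = 6L, segments_per_participant = 60L,
                         effects = cohort_effects(), noise_sd = 2,
                         mesh_pitch = 25, r = segment_radius(), delta = 100,
                         topo_subsample = 1000L, topo_max_filtration = 100,
                         tasks = c("type", "gender", "age", "participant"),
                         families = c("baseline", "curvature", "topological",
                                      "all"),
                         models = c("svm", "lr"),
                         schemes = c("random", "logo"),
                         n_splits = 50L, prune_threshold = 0.65,
                         n_permutations = 30L, importance_task = "type") {
  structure(as.list(environment()), class = "study_config")
}

#' Read a study configuration from JSON
#'
#' @param path JSON file with (a subset of) [study_config()] fields; the
#'   `effects` field may be a named list of [cohort_effects()] arguments.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(vals$effects)) {
    vals$effects <- do.call(cohort_effects, as.list(vals$effects))
  }
  do.call(study_config, vals)
}

# sweep + label one participant surface and cap the per-class segment counts
# at the study's class proportions
collect_segments <- function(surface, config, target_counts, seed) {
  segs <- sweep_surface(surface$mesh, r = config$r, delta = config$delta,
                        seed = seed)
  segs <- label_segments(segs, surface)
  labels <- vapply(segs, `[[`, "", "label")
  keep <- integer(0)
  with_seed(derive_seed(seed, 31L), {
    for (cl in names(target_counts)) {
      idx <- which(labels == cl)
      n_take <- min(length(idx), target_counts[[cl]])
      if (n_take > 0L) keep <- c(keep, sample(idx, n_take))
    }
  })
  segs[sort(keep)]
}

#' Run the full synthetic papillae study
#'
#' End-to-end pipeline: [generate_cohort()] -> [sweep_surface()] +
#' [label_segments()] per participant -> [assemble_features()] ->
#' [prune_correlated()] -> [evaluate_task()] for every requested task x
#' feature family x model x split scheme -> [permutation_importance()] ->
#' [map_papillae()] on one cohort surface. Deterministic given
#' (config, seed). With `out_dir` set, all tables plus a summary JSON are
#' written as artifacts.
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @param out_dir optional artifact directory.
#' @param map_surface index of the cohort surface to map.
#' @return A `papilla_study`: cohort metadata, feature table, removal log,
#'   results tibble (one row per evaluation), the evaluation objects, the
#'   importance report and the papillae map.
#' @export
run_study <- function(config = study_config(), seed = 1, out_dir = NULL,
                      map_surface = 1L) {
  stage <- "cohort"
  result <- tryCatch({
    cohort <- generate_cohort(
      n_participants = config$n_participants,
      segments_per_participant = config$segments_per_participant,
      effects = config$effects, noise_sd = config$noise_sd,
      mesh_pitch = config$mesh_pitch, seed = derive_seed(seed, 1L))

    stage <- "segmentation"
    frac <- c(fungiform = 414, filiform = 1489, none = 190) / 2093
    target <- round(config$segments_per_participant * frac)
    segments <- list()
    for (i in seq_along(cohort$surfaces)) {
      segs <- collect_segments(cohort$surfaces[[i]], config, target,
                               seed = derive_seed(seed, 100L + i))
      segments <- c(segments, segs)
    }
    if (length(segments) == 0L) stop("sweep produced no segments")

    stage <- "features"
    feats <- suppressWarnings(assemble_features(
      segments, topo_subsample = config$topo_subsample,
      max_filtration = config$topo_max_filtration,
      seed = derive_seed(seed, 2L)))
    pruned <- prune_correlated(feats, config$prune_threshold)

    stage <- "evaluation"
    grid <- tidyr::expand_grid(task = config$tasks, family = config$families,
                               model = config$models, scheme = config$schemes) |>
      # participant identity cannot be evaluated leave-one-participant-out
      dplyr::filter(!(.data$task == "participant" & .data$scheme == "logo"))
    evals <- purrr::pmap(grid, function(task, family, model, scheme) {
      evaluate_task(pruned, task = task, family = family, model = model,
                    scheme = scheme, n_splits = config$n_splits,
                    seed = derive_seed(seed, 3L))
    })
    results <- dplyr::bind_rows(purrr::map(evals, glance))

    stage <- "importance"
    importance <- permutation_importance(
      pruned, task = config$importance_task, family = "all", model = "svm",
      scheme = "random", n_splits = config$n_splits,
      n_permutations = config$n_permutations, seed = derive_seed(seed, 4L))

    stage <- "mapping"
    classifier <- train_type_classifier(feats, model = "svm",
                                        prune_threshold = config$prune_threshold)
    map <- map_papillae(cohort$surfaces[[map_surface]], classifier,
                        r = config$r, delta = config$delta,
                        topo_subsample = config$topo_subsample,
                        max_filtration = config$topo_max_filtration,
                        seed = derive_seed(seed, 5L),
                        surface_id = cohort$metadata$participant[map_surface])

    structure(list(metadata = cohort$metadata, feature_table = feats,
                   pruned_table = pruned,
                   removal_log = attr(pruned, "removal_log"),
                   results = results, evals = evals,
                   importance = importance, classifier = classifier,
                   map = map, config = config, seed = seed),
              class = "papilla_study")
  }, error = function(e) {
    stop("study failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) write_study_artifacts(result, out_dir)
  result
}

write_study_artifacts <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$feature_table, file.path(out_dir, "features.csv"),
            row.names = FALSE)
  write.csv(study$results, file.path(out_dir, "results.csv"),
            row.names = FALSE)
  write.csv(study$importance$importances,
            file.path(out_dir, "importance.csv"), row.names = FALSE)
  write.csv(study$map$detections, file.path(out_dir, "map.csv"),
            row.names = FALSE)
  cfg <- study$config
  cfg$effects <- unclass(cfg$effects)
  summary <- list(
    seed = study$seed,
    config = unclass(cfg),
    n_segments = nrow(study$feature_table),
    removed_features = study$removal_log$removed,
    results = study$results,
    family_importance = study$importance$family_importance,
    map_counts = as.list(study$map$counts))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.papilla_study <- function(x, ...) {
  cat(sprintf("<papilla_study> %d participants, %d segments, %d evaluations\n",
              nrow(x$metadata), nrow(x$feature_table), nrow(x$results)))
  print(x$results, n = Inf)
  invisible(x)
}
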