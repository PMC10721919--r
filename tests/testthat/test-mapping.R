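test_that("assemble_features produces a labelled, complete table", {
  s <- generate_surface(width = 3000, depth = 3000,
                        counts = c(fungiform = 1, filiform = 4),
                        min_separation = 100, seed = 21,
                        participant = participant_profile("P01", "F", 26))
  segs <- label_segments(sweep_surface(s$mesh, seed = 3), s)
  tab <- suppressWarnings(assemble_features(segs, topo_subsample = 100,
                                            seed = 5))
  expect_true(all(c("segment", "type", "participant", "gender", "age",
                    "age_group") %in% names(tab)))
  expect_true(all(feature_families()$feature %in% names(tab)))
  feats <- tab[, feature_families()$feature]
  expect_false(anyNA(feats))
  expect_true(all(tab$type %in% c("fungiform", "filiform", "none")))
  expect_identical(tab$participant[1], "P01")
})

test_that("a trained type classifier maps a surface deterministically", {
  s <- generate_surface(width = 3000, depth = 3000,
                        counts = c(fungiform = 1, filiform = 4),
                        min_separation = 100, seed = 21,
                        participant = participant_profile("P01", "F", 26))
  segs <- label_segments(sweep_surface(s$mesh, seed = 3), s)
  tab <- suppressWarnings(assemble_features(segs, topo_subsample = 100,
                                            seed = 5))
  clf <- train_type_classifier(tab, model = "svm")
  expect_s3_class(clf, "papilla_classifier")

  map1 <- map_papillae(s, clf, topo_subsample = 100, seed = 9,
                       surface_id = "S1")
  map2 <- map_papillae(s, clf, topo_subsample = 100, seed = 9,
                       surface_id = "S1")
  expect_identical(map1$detections, map2$detections)
  expect_true(all(map1$detections$type %in% c("fungiform", "filiform")))
  expect_true(all(map1$detections$confidence >= 0 &
                    map1$detections$confidence <= 1))
  expect_identical(names(tidy(map1)),
                   c("surface_id", "x", "y", "z", "type", "confidence"))

  # schema error on missing feature columns
  bad <- tab[, setdiff(names(tab), "height_um")]
  expect_error(predict(clf, bad), "schema error")
})

test_that("run_study produces a coherent report at desk scale", {
  cfg <- study_config(n_participants = 2L, segments_per_participant = 15L,
                      topo_subsample = 100L, n_splits = 3L,
                      n_permutations = 3L, tasks = c("type", "participant"),
                      families = c("baseline", "all"), models = "svm",
                      schemes = c("random", "logo"))
  out_dir <- withr::local_tempdir()
  st <- run_study(cfg, seed = 31, out_dir = out_dir)
  expect_s3_class(st, "papilla_study")

  # grid: type x {baseline, all} x {random, logo} + participant x 2 x random
  expect_identical(nrow(st$results), 6L)
  expect_false(any(st$results$task == "participant" &
                     st$results$scheme == "logo"))
  expect_true(all(st$results$balanced_accuracy >= 0 &
                    st$results$balanced_accuracy <= 1))
  expect_identical(st$importance$task, "type")
  expect_s3_class(st$map, "papillae_map")

  # artifacts written
  expect_true(all(file.exists(file.path(out_dir,
                                        c("features.csv", "results.csv",
                                          "importance.csv", "map.csv",
                                          "summary.json")))))
  summ <- jsonlite::read_json(file.path(out_dir, "summary.json"),
                              simplifyVector = TRUE)
  expect_identical(summ$seed, 31L)
  expect_identical(summ$n_segments, nrow(st$feature_table))
})

test_that("study configurations round-trip through JSON", {
  cfg <- study_config(n_participants = 3L, topo_subsample = 150L,
                      effects = cohort_effects(gender_sharpness = 0.5),
                      tasks = "type", models = "svm")
  f <- withr::local_tempfile(fileext = ".json")
  plain <- unclass(cfg)
  plain$effects <- unclass(plain$effects)
  jsonlite::write_json(plain, f, auto_unbox = TRUE, digits = NA)
  cfg2 <- read_study_config(f)
  expect_identical(cfg2$n_participants, 3L)
  expect_identical(cfg2$topo_subsample, 150L)
  expect_equal(cfg2$effects$gender_sharpness, 0.5)
  expect_identical(cfg2$tasks, "type")
})

test_that("autoplot methods return renderable ggplot objects", {
  withr::with_seed(41, pts <- matrix(runif(240, 0, 100), ncol = 3))
  dg <- rips_persistence(pts)
  p1 <- ggplot2::autoplot(dg)
  p2 <- ggplot2::autoplot(dg, type = "barcode")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
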