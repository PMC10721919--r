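test_that("unit square has the classic H1 bar (1, sqrt(2))", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  dg <- rips_persistence(sq)
  h1 <- dg[dg$dimension == 1L, ]
  expect_identical(nrow(h1), 1L)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))
  # three H0 merges at distance 1
  expect_equal(dg$death[dg$dimension == 0L], rep(1, 3))
})

test_that("H0 deaths equal single-linkage merge heights on random clouds", {
  withr::with_seed(101, {
    for (k in 1:15) {
      pts <- matrix(runif(3 * sample(10:120, 1), 0, 500), ncol = 3)
      dg <- rips_persistence(pts, max_dim = 0L)
      expect_equal(sort(dg$death[dg$dimension == 0L]),
                   oracle_h0_deaths(pts), tolerance = 1e-12)
    }
  })
})

test_that("H1 bars match the full boundary-matrix reduction oracle", {
  withr::with_seed(202, {
    for (k in 1:8) {
      pts <- matrix(runif(3 * sample(8:18, 1), 0, 100), ncol = 3)
      dg <- rips_persistence(pts)
      want <- oracle_rips_diagram(pts)
      got <- dg[dg$dimension == 1L, c("birth", "death")]
      got <- as.matrix(got[order(got$birth, got$death), ])
      storage.mode(got) <- "double"
      expect_equal(unname(got), unname(want$h1), tolerance = 1e-12)
      expect_equal(sort(dg$death[dg$dimension == 0L]),
                   want$h0_deaths[want$h0_deaths > 0], tolerance = 1e-12)
    }
  })
})

test_that("noisy circle sample has one dominant H1 class", {
  withr::with_seed(7, {
    t <- runif(60, 0, 2 * pi)
    pts <- cbind(100 * cos(t), 100 * sin(t), 0) + matrix(rnorm(180, 0, 2),
                                                         ncol = 3)
  })
  dg <- rips_persistence(pts)
  h1 <- dg[dg$dimension == 1L, ]
  pers <- h1$death - h1$birth
  expect_gte(nrow(h1), 1L)
  second <- if (nrow(h1) >= 2L) sort(pers, decreasing = TRUE)[2L] else 0
  expect_gt(max(pers), 3 * second)
  expect_gt(max(pers), 50)
})

test_that("persistent entropy matches its closed forms", {
  dg_k <- make_diagram(rep(0L, 5), rep(0, 5), rep(2, 5))
  expect_equal(persistent_entropy(dg_k, 0L), log(5))
  dg_1 <- make_diagram(0L, 0, 7)
  expect_equal(persistent_entropy(dg_1, 0L), 0)
  expect_lte(persistent_entropy(dg_k, 0L, shannon = FALSE), 0)
  expect_error(persistent_entropy(dg_1, 1L), "undefined-entropy")
})

test_that("Wasserstein and bottleneck amplitudes match closed forms", {
  dg <- make_diagram(c(0L, 0L), c(0, 0), c(3, 4))
  expect_equal(wasserstein_amplitude(dg, 0L), sqrt(2) / 2 * 5)
  expect_equal(bottleneck_amplitude(dg, 0L), sqrt(2) / 2 * 4)
  dg_b <- make_diagram(0L, 0, 4)
  expect_equal(bottleneck_amplitude(dg_b, 0L), 2 * sqrt(2))
  expect_equal(wasserstein_amplitude(dg_b, 0L, p = 1), sqrt(2) / 2 * 4)
  # empty dimension -> 0
  expect_equal(wasserstein_amplitude(dg_b, 1L), 0)
})

test_that("landscape amplitude of one tent matches its analytic L2 norm", {
  # bar (0, 2s): lambda_1 is a tent of height s; its L2 norm is s^{3/2} sqrt(2/3)
  for (s in c(1, 5, 40)) {
    dg <- make_diagram(0L, 0, 2 * s)
    expect_equal(landscape_amplitude(dg, 0L, grid_size = 4000L),
                 s^1.5 * sqrt(2 / 3), tolerance = 0.01)
  }
  # scaling: doubling the bar scales the norm by 2^(3/2)
  a1 <- landscape_amplitude(make_diagram(0L, 0, 2), 0L, grid_size = 4000L)
  a2 <- landscape_amplitude(make_diagram(0L, 0, 4), 0L, grid_size = 4000L)
  expect_equal(a2 / a1, 2^1.5, tolerance = 0.01)
})

test_that("persistence image amplitude is positive and scale-monotone", {
  d_small <- make_diagram(c(1L, 1L), c(10, 20), c(15, 60))
  expect_gt(image_amplitude(d_small, 1L), 0)
  expect_equal(image_amplitude(d_small, 0L), 0)  # empty dimension
})

test_that("short bars count only the (0, 10] persistence window", {
  dg <- make_diagram(rep(0L, 4), c(0, 0, 0, 0), c(5, 10, 10.5, 200))
  expect_identical(short_bars(dg, 0L), 2L)
  expect_identical(short_bars(dg, 0L, lo = 0, hi = 300), 4L)
  expect_identical(short_bars(dg, 1L), 0L)
})

test_that("subsampling is deterministic and bounded", {
  withr::with_seed(5, pts <- matrix(runif(900), ncol = 3))
  s1 <- subsample_points(pts, 50, seed = 9)
  s2 <- subsample_points(pts, 50, seed = 9)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 50L)
  expect_identical(subsample_points(pts, 1000, seed = 9), pts)
})

test_that("topo_features returns the twelve named columns deterministically", {
  withr::with_seed(64, pts <- matrix(runif(900, 0, 300), ncol = 3))
  tf1 <- topo_features(pts, n = 120, seed = 3)
  tf2 <- topo_features(pts, n = 120, seed = 3)
  expect_identical(tf1, tf2)
  expect_identical(names(tf1),
                   feature_families()$feature[
                     feature_families()$family == "topological"])
  expect_true(all(vapply(tf1, is.numeric, TRUE)))
})
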