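test_that("compute_radius follows the grow-by-10 procedure", {
  m <- c(0, 0, 0)
  # all points inside the initial 100 um guess
  close_pts <- matrix(rnorm(90, 0, 20), ncol = 3)
  expect_equal(compute_radius(close_pts, m), 100)
  # 100 points at distance 205 -> first grid step >= 205 is 210
  sph <- matrix(rnorm(300), ncol = 3)
  sph <- sph / sqrt(rowSums(sph^2)) * 205
  expect_equal(compute_radius(sph, m), 210)
})

test_that("compute_radius equals the brute-force grid oracle", {
  withr::with_seed(31, {
    for (k in 1:20) {
      pts <- matrix(runif(3 * sample(20:300, 1), -400, 400), ncol = 3)
      m <- pts[sample(nrow(pts), 1), ]
      expect_equal(compute_radius(pts, m), oracle_radius(pts, m))
    }
  })
})

test_that("compute_height measures a point above a plane", {
  withr::with_seed(12, {
    plane <- cbind(runif(500, -500, 500), runif(500, -500, 500), 0)
  })
  m <- c(0, 0, 300)
  expect_equal(compute_height(rbind(plane, m), m, r_seg = 600, seed = 4), 300,
               tolerance = 1e-6)
  # a point on the plane has height ~ 0
  m2 <- c(10, 10, 0)
  expect_lt(compute_height(rbind(plane, m2), m2, r_seg = 600, seed = 4), 1e-6)
})

test_that("compute_height recovers a hemisphere's height from its base", {
  withr::with_seed(13, {
    u <- matrix(rnorm(1500), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    u[, 3] <- abs(u[, 3])
    hemi <- u * 400
    ground <- cbind(runif(1500, -800, 800), runif(1500, -800, 800), 0)
    ground <- ground[sqrt(rowSums(ground[, 1:2]^2)) > 400, ]
  })
  pts <- rbind(hemi, ground)
  h <- compute_height(pts, m = c(0, 0, 400), r_seg = 900, seed = 8)
  expect_gte(h, 380)
  expect_lte(h, 420)
})

test_that("Gauss-Bonnet holds on closed sphere and torus meshes", {
  sph <- make_uv_sphere(R = 500, n_lat = 30, n_lon = 40)
  fs <- discrete_curvatures(sph)
  expect_false(any(fs$boundary))
  expect_equal(sum(fs$angle_defect), 4 * pi, tolerance = 1e-9)

  tor <- make_torus(R = 600, r = 200, n_major = 36, n_minor = 18)
  ft <- discrete_curvatures(tor)
  expect_equal(sum(ft$angle_defect) / (4 * pi), 0, tolerance = 1e-9)
})

test_that("sphere curvatures match 1/R^2 and 1/R", {
  R <- 500
  sph <- make_uv_sphere(R = R, n_lat = 40, n_lon = 60)
  f <- discrete_curvatures(sph)
  expect_equal(stats::median(f$gaussian), 1 / R^2, tolerance = 0.05)
  expect_equal(stats::median(abs(f$mean)), 1 / R, tolerance = 0.05)
  # convex closed surface: positive mean curvature under outward normals
  expect_gt(mean(f$mean > 0), 0.99)
})

test_that("icosahedron vertices all carry angle deficit pi/3", {
  ico <- make_icosahedron()
  f <- discrete_curvatures(ico)
  expect_equal(f$angle_defect, rep(pi / 3, 12), tolerance = 1e-12)
})

test_that("boundary vertices are excluded from curvature statistics", {
  m <- make_grid_mesh(400, 400, 50)
  f <- discrete_curvatures(m)
  expect_true(all(is.na(f$gaussian[f$boundary])))
  expect_setequal(which(f$boundary), boundary_vertices(m))
  # single triangle: every vertex is a boundary vertex
  tri <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  expect_error(curvature_summary(discrete_curvatures(tri)), "empty-field")
})

test_that("curvature summary ratios are well-defined and bounded", {
  sp <- papilla_spec("fungiform", center = c(750, 750))
  m <- make_grid_mesh(1500, 1500, 25, zfun = papilla_heightfield(sp))
  cs <- curvature_summary(discrete_curvatures(m))
  expect_gte(cs$k_ratio, 0)
  expect_lte(cs$k_ratio, 1)
  expect_gte(cs$k_positiveratio, 0)
  expect_lte(cs$k_positiveratio, 1)
  expect_gt(cs$gauss_max, 0)   # dome apex
  expect_lt(cs$gauss_min, 0)   # rim annulus
  # the apex is the most positively curved region
  f <- discrete_curvatures(m)
  apex <- which.min(rowSums(sweep(m$vertices[, 1:2, drop = FALSE], 2,
                                  c(750, 750))^2))
  expect_gt(f$gaussian[apex], 0)
})

test_that("fungiform rim band is mostly negatively curved", {
  sp <- papilla_spec("fungiform", center = c(750, 750))
  m <- make_grid_mesh(1500, 1500, 25, zfun = papilla_heightfield(sp))
  f <- discrete_curvatures(m)
  rho <- sqrt(rowSums(sweep(m$vertices[, 1:2, drop = FALSE], 2,
                            c(750, 750))^2))
  # the dome meets the flat sheet in a crease ring at rho = R; negative
  # curvature concentrates within one mesh pitch of that ring
  band <- which(rho >= 439 - 25 & rho <= 439 + 25 & !f$boundary)
  expect_gte(mean(f$gaussian[band] < 0), 0.6)
})

test_that("geometry_features recovers planted cap height and radius", {
  sp <- papilla_spec("fungiform", center = c(1200, 1200), base_radius = 400,
                     height = 240)
  m <- make_grid_mesh(2400, 2400, 25, zfun = papilla_heightfield(sp))
  p_idx <- which.min(rowSums(sweep(m$vertices, 2, c(1100, 1200, 0))^2))
  seg <- extract_segment(m, p_idx, seed = 5)
  gf <- geometry_features(seg, seed = 6)
  expect_equal(gf$height_um, 240, tolerance = 0.1)
  expect_equal(gf$radius_um, 400, tolerance = 0.1)
  expect_identical(ncol(gf), 8L)
})
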