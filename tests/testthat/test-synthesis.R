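test_that("papilla height fields honour their boundary conditions", {
  sp <- papilla_spec("fungiform", center = c(100, -50), base_radius = 439,
                     height = 300)
  hf <- papilla_heightfield(sp)
  expect_equal(hf(100, -50), 300)
  expect_equal(hf(100 + 439, -50), 0)
  expect_equal(hf(100, -50 + 500), 0)
  # dome decreases radially
  r <- seq(0, 439, length.out = 50)
  expect_true(all(diff(hf(100 + r, -50)) <= 0))
})

test_that("sharper fungiform specs have higher peak Gaussian curvature", {
  # curvature at the apex vertex, not the mesh-wide max: at low sharpness the
  # dome meets the flat sheet with a slope break, and the crease along the rim
  # would otherwise dominate the comparison
  apex_k <- function(sharpness) {
    sp <- papilla_spec("fungiform", center = c(600, 600), sharpness = sharpness)
    m <- make_grid_mesh(1200, 1200, 20, zfun = papilla_heightfield(sp))
    i <- which.min((m$vertices[, 1] - 600)^2 + (m$vertices[, 2] - 600)^2)
    discrete_curvatures(m)$gaussian[i]
  }
  k1 <- apex_k(1)
  k2 <- apex_k(2)
  expect_gt(k2, k1)
  # the dome h * (1 - (rho/R)^2)^p has analytic apex Gaussian curvature
  # (2 h p / R^2)^2; defaults h = 250, R = 439
  expect_equal(k1, (2 * 250 * 1 / 439^2)^2, tolerance = 0.05)
  expect_equal(k2, (2 * 250 * 2 / 439^2)^2, tolerance = 0.05)
})

test_that("filiform crown has exactly spike_count + 1 strict local maxima", {
  sp <- papilla_spec("filiform", center = c(300, 300), spike_count = 6L)
  hf <- papilla_heightfield(sp)
  xs <- seq(0, 600, by = 4)
  z <- outer(xs, xs, function(x, y) hf(x, y))
  expect_identical(count_local_maxima(z), 7L)

  sp4 <- papilla_spec("filiform", center = c(300, 300), spike_count = 4L)
  z4 <- outer(xs, xs, function(x, y) papilla_heightfield(sp4)(x, y))
  expect_identical(count_local_maxima(z4), 5L)
})

test_that("fungiform specs reject spikes and invalid dimensions", {
  expect_error(papilla_spec("fungiform", spike_count = 3L), "spike_count")
  expect_error(papilla_spec("fungiform", base_radius = -1))
  expect_error(papilla_spec("filiform", height = 0))
})

test_that("papilla-free noise-free surface is the pure undulation", {
  s <- generate_surface(width = 2000, depth = 2000,
                        counts = c(fungiform = 0, filiform = 0),
                        noise_sd = 0, undulation_amplitude = 30, seed = 5)
  zr <- range(s$mesh$vertices[, 3])
  expect_lte(diff(zr), 2 * 30 + 1e-9)
  expect_gt(diff(zr), 30)  # the undulation is actually there
  expect_identical(nrow(s$papillae), 0L)
})

test_that("surface generation is deterministic and annotations match geometry", {
  cnt <- c(fungiform = 2, filiform = 5)
  s1 <- generate_surface(width = 3500, depth = 3500, counts = cnt, seed = 42)
  s2 <- generate_surface(width = 3500, depth = 3500, counts = cnt, seed = 42)
  expect_identical(s1$mesh$vertices, s2$mesh$vertices)
  expect_identical(s1$papillae, s2$papillae)

  expect_identical(sum(s1$papillae$type == "fungiform"), 2L)
  expect_identical(sum(s1$papillae$type == "filiform"), 5L)

  # each planted apex rises at least half its spec height above the base
  rho <- function(p) sqrt((s1$mesh$vertices[, 1] - p$x)^2 +
                            (s1$mesh$vertices[, 2] - p$y)^2)
  for (i in seq_len(nrow(s1$papillae))) {
    p <- s1$papillae[i, ]
    d <- rho(p)
    top_z <- max(s1$mesh$vertices[d <= 60, 3])
    base_z <- stats::median(
      s1$mesh$vertices[d > p$base_radius & d <= p$base_radius + 200, 3])
    expect_gte(top_z - base_z, 0.5 * p$height)
  }
})

test_that("unachievable packing density raises a placement error", {
  expect_error(
    generate_surface(width = 1200, depth = 1200,
                     counts = c(fungiform = 8, filiform = 0), seed = 1),
    "placement error")
})

test_that("cohorts are deterministic with plausible demographics", {
  c1 <- generate_cohort(n_participants = 4, segments_per_participant = 10,
                        seed = 3)
  c2 <- generate_cohort(n_participants = 4, segments_per_participant = 10,
                        seed = 3)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$surfaces[[2]]$mesh$vertices,
                   c2$surfaces[[2]]$mesh$vertices)

  md <- c1$metadata
  expect_true(all(md$age >= 22 & md$age <= 37))
  expect_identical(md$age_group, ifelse(md$age <= 28, "young", "old"))
  expect_true(all(md$age_group == "young" | md$age >= 29))
  expect_gte(length(unique(md$participant)), 4L)
  # latent offsets distinguish participants
  expect_gte(length(unique(md$sharpness_mult)), 4L)

  expect_error(generate_cohort(n_participants = 1), "argument error")
})

test_that("the gender sharpness effect shifts female profiles upward", {
  big <- generate_cohort(n_participants = 12, segments_per_participant = 10,
                         effects = cohort_effects(gender_sharpness = 1.5,
                                                  age_sharpness = 0,
                                                  participant_sharpness_sd = 0.05,
                                                  participant_size_sd = 0.05),
                         seed = 11)
  md <- big$metadata
  expect_gt(mean(md$sharpness_mult[md$gender == "F"]),
            mean(md$sharpness_mult[md$gender == "M"]))
})

test_that("jitter_scale 0 plants papillae exactly at specification", {
  s <- generate_surface(width = 3000, depth = 3000,
                        counts = c(fungiform = 2, filiform = 3),
                        min_separation = 100, jitter_scale = 0, seed = 11)
  fungi <- s$papillae[s$papillae$type == "fungiform", ]
  fili <- s$papillae[s$papillae$type == "filiform", ]
  expect_true(all(fungi$base_radius == fungi$base_radius[1]))
  expect_true(all(fungi$height == fungi$height[1]))
  expect_true(all(fili$base_radius == fili$base_radius[1]))
  expect_true(all(fili$spike_count == fili$spike_count[1]))
  # jittered surfaces vary
  s2 <- generate_surface(width = 3000, depth = 3000,
                         counts = c(fungiform = 2, filiform = 3),
                         min_separation = 100, seed = 11)
  fungi2 <- s2$papillae[s2$papillae$type == "fungiform", ]
  expect_false(fungi2$base_radius[1] == fungi2$base_radius[2])
})
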