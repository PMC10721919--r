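test_that("tri_mesh validation rejects malformed meshes", {
  v <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), ncol = 3, byrow = TRUE)
  expect_s3_class(tri_mesh(v, rbind(c(1, 2, 3))), "tri_mesh")
  expect_error(tri_mesh(v, rbind(c(1, 2, 4))), "index")
  expect_error(tri_mesh(v, rbind(c(1, 2, 2))), "repeat")
  expect_error(tri_mesh(v, rbind(c(1, 2, 3), c(3, 1, 2))), "duplicate")
})

test_that("grid mesh satisfies the Euler relation of a disk", {
  m <- make_grid_mesh(400, 300, 50)
  V <- nrow(m$vertices)
  Fc <- nrow(m$triangles)
  E <- nrow(mesh_edges(m))
  expect_identical(V - E + Fc, 1L)  # chi of a disk
})

test_that("boundary vertices of a grid sheet are exactly the perimeter", {
  m <- make_grid_mesh(300, 300, 50)
  b <- boundary_vertices(m)
  onperim <- which(m$vertices[, 1] %in% c(0, 300) |
                     m$vertices[, 2] %in% c(0, 300))
  expect_setequal(b, onperim)
})

test_that("vertex normals of a flat sheet point up with unit length", {
  m <- make_grid_mesh(200, 200, 50)
  nrm <- vertex_normals(m)
  expect_equal(sqrt(rowSums(nrm^2)), rep(1, nrow(nrm)), tolerance = 1e-12)
  expect_equal(nrm[, 3], rep(1, nrow(nrm)), tolerance = 1e-12)
})

test_that("submesh keeps induced triangles and reindexes them validly", {
  m <- make_grid_mesh(300, 300, 50)
  keep <- radius_query(m$vertices, c(150, 150, 0), 120)
  s <- submesh(m, keep)
  expect_identical(nrow(s$vertices), length(keep))
  expect_true(all(s$triangles >= 1L & s$triangles <= nrow(s$vertices)))
  expect_no_error(validate_mesh(s))
  # every sub-triangle is a triangle of the parent with all corners kept
  orig <- m$triangles[apply(matrix(m$triangles %in% keep,
                                   ncol = 3L), 1L, all), , drop = FALSE]
  expect_identical(nrow(s$triangles), nrow(orig))
})

test_that("ASCII PLY round-trip preserves geometry bit-for-bit", {
  m <- make_grid_mesh(200, 150, 50, zfun = function(x, y) sin(x / 40) * 17.3)
  f <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, f)
  m2 <- read_mesh(f)
  expect_identical(m2$vertices, unname(m$vertices))
  expect_identical(m2$triangles, m$triangles)
})

test_that("OBJ round-trip preserves topology exactly and geometry precisely", {
  m <- make_grid_mesh(200, 150, 50, zfun = function(x, y) cos(y / 31) * 5)
  f <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, f)
  m2 <- read_mesh(f)
  expect_identical(m2$triangles, m$triangles)
  expect_equal(m2$vertices, unname(m$vertices), tolerance = 1e-15)
})

test_that("binary little-endian PLY with float32 vertices is read correctly", {
  v <- matrix(c(0, 0, 0, 100, 0, 0, 0, 100, 0, 100, 100, 25), ncol = 3,
              byrow = TRUE)
  tris <- rbind(c(1L, 2L, 3L), c(2L, 4L, 3L))
  f <- withr::local_tempfile(fileext = ".ply")
  con <- file(f, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "comment synthetic fixture",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 2",
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeBin(as.numeric(t(v)), con, size = 4L, endian = "little")
  for (i in 1:2) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(tris[i, ] - 1L), con, size = 4L, endian = "little")
  }
  close(con)
  m <- read_mesh(f)
  expect_equal(m$vertices, v, tolerance = 1e-6)
  expect_identical(m$triangles, tris)
})

test_that("PLY reader ignores extra vertex properties and rejects quads", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 3",
               "property double x", "property double y", "property double z",
               "property double quality",
               "element face 1",
               "property list uchar int vertex_indices",
               "end_header",
               "0 0 0 0.5", "1 0 0 0.5", "0 1 0 0.5",
               "3 0 1 2"), f)
  m <- read_mesh(f)
  expect_identical(dim(m$vertices), c(3L, 3L))

  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property double x", "property double y", "property double z",
               "element face 1",
               "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), f)
  expect_error(read_mesh(f), "non-triangular")
})

test_that("radius_query returns the closed ball and matches a direct scan", {
  withr::with_seed(4, {
    pts <- matrix(runif(300, 0, 100), ncol = 3)
  })
  pts <- rbind(pts, c(50, 50, 50) + c(30, 0, 0))  # exactly on the boundary
  got <- radius_query(pts, c(50, 50, 50), 30)
  want <- which(sqrt(rowSums(sweep(pts, 2, c(50, 50, 50))^2)) <= 30)
  expect_identical(got, want)
  expect_true(nrow(pts) %in% got)
})

test_that("connected components over mesh edges match a BFS oracle", {
  m <- make_grid_mesh(500, 500, 50)
  edges <- mesh_edges(m)
  withr::with_seed(8, {
    for (k in 1:5) {
      subset <- sample(nrow(m$vertices), 60)
      start <- subset[1]
      sub_edges <- edges[edges[, 1] %in% subset & edges[, 2] %in% subset, ,
                         drop = FALSE]
      want <- intersect(oracle_component(sub_edges, nrow(m$vertices), start),
                        subset)
      got <- connected_component_of(m, subset, start)
      expect_setequal(got, want)
    }
  })
})

test_that("RANSAC recovers a plane under structured outliers", {
  withr::with_seed(21, {
    base <- cbind(runif(400, 0, 1000), runif(400, 0, 1000), rnorm(400, 50, 3))
    bump <- cbind(runif(60, 400, 600), runif(60, 400, 600), runif(60, 150, 400))
  })
  fit <- ransac_fit_plane(rbind(base, bump), seed = 7)
  # normal within 2 degrees of +/- z, offset near 50
  expect_gt(abs(fit$normal[3]), cos(2 * pi / 180))
  expect_equal(abs(fit$offset), 50, tolerance = 0.1)
  expect_gt(fit$n_inliers, 350)
  # degenerate input errors
  line <- cbind(1:10, 1:10, 1:10)
  expect_error(ransac_fit_plane(line, seed = 1), "degenerate")
})
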