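# Closed and open reference meshes with known analytic geometry.

# Closed UV sphere of radius R: two pole fans plus quad strips. Outward
# orientation (counter-clockwise seen from outside).
make_uv_sphere <- function(R = 500, n_lat = 24L, n_lon = 36L,
                           center = c(0, 0, 0)) {
  stopifnot(n_lat >= 3L, n_lon >= 3L)
  theta <- pi * seq_len(n_lat - 1L) / n_lat
  phi <- 2 * pi * (seq_len(n_lon) - 1L) / n_lon
  ring <- function(t) cbind(R * sin(t) * cos(phi), R * sin(t) * sin(phi),
                            rep(R * cos(t), n_lon))
  v <- rbind(c(0, 0, R), do.call(rbind, lapply(theta, ring)), c(0, 0, -R))
  v <- sweep(v, 2L, center, "+")
  np <- 1L
  sp <- nrow(v)
  idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  tris <- list()
  for (j in seq_len(n_lon)) {
    tris[[length(tris) + 1L]] <- c(np, idx(1L, j), idx(1L, j + 1L))
    tris[[length(tris) + 1L]] <- c(sp, idx(n_lat - 1L, j + 1L),
                                   idx(n_lat - 1L, j))
  }
  for (i in seq_len(n_lat - 2L)) {
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c2 <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      tris[[length(tris) + 1L]] <- c(a, c2, b)
      tris[[length(tris) + 1L]] <- c(b, c2, d)
    }
  }
  tri_mesh(v, do.call(rbind, tris))
}

# Closed torus: tube radius r around a circle of radius R in the xy plane.
make_torus <- function(R = 600, r = 200, n_major = 40L, n_minor = 20L) {
  u <- 2 * pi * (seq_len(n_major) - 1L) / n_major
  w <- 2 * pi * (seq_len(n_minor) - 1L) / n_minor
  v <- matrix(0, n_major * n_minor, 3L)
  for (i in seq_len(n_major)) {
    for (j in seq_len(n_minor)) {
      v[(i - 1L) * n_minor + j, ] <- c(
        (R + r * cos(w[j])) * cos(u[i]),
        (R + r * cos(w[j])) * sin(u[i]),
        r * sin(w[j]))
    }
  }
  idx <- function(i, j) ((i - 1L) %% n_major) * n_minor + ((j - 1L) %% n_minor) + 1L
  tris <- list()
  for (i in seq_len(n_major)) {
    for (j in seq_len(n_minor)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c2 <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
      tris[[length(tris) + 1L]] <- c(a, b, c2)
      tris[[length(tris) + 1L]] <- c(b, d, c2)
    }
  }
  tri_mesh(v, do.call(rbind, tris))
}

# Regular icosahedron with circumradius scaled by `scale`; every vertex has
# five equilateral incident triangles, so its angle deficit is pi/3.
make_icosahedron <- function(scale = 100) {
  g <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  g, 0), c(1,  g, 0), c(-1, -g, 0), c(1, -g, 0),
    c(0, -1,  g), c(0, 1,  g), c(0, -1, -g), c(0, 1, -g),
    c(g, 0, -1), c(g, 0, 1), c(-g, 0, -1), c(-g, 0, 1))
  v <- v / sqrt(1 + g^2) * scale
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  tri_mesh(v, f)
}

# Open grid sheet z = zfun(x, y) on [0, width] x [0, depth].
make_grid_mesh <- function(width = 1000, depth = 1000, pitch = 50,
                           zfun = function(x, y) 0 * x) {
  xs <- seq(0, width, by = pitch)
  ys <- seq(0, depth, by = pitch)
  g <- expand.grid(x = xs, y = ys)
  v <- cbind(g$x, g$y, zfun(g$x, g$y))
  nx <- length(xs)
  ny <- length(ys)
  tris <- list()
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      a <- (j - 1L) * nx + i
      b <- a + 1L
      c2 <- a + nx
      d <- c2 + 1L
      tris[[length(tris) + 1L]] <- c(a, b, c2)
      tris[[length(tris) + 1L]] <- c(b, d, c2)
    }
  }
  tri_mesh(v, do.call(rbind, tris))
}
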