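# Vietoris-Rips persistent homology of segment point clouds and the twelve
# one-number diagram summaries used as the topological feature family.

#' Uniform subsample of a point cloud
#'
#' Uniform random sample without replacement of `min(n, nrow(points))` rows;
#' the full cloud is returned unchanged when it is already small enough.
#' Deterministic given `seed`.
#'
#' @param points numeric matrix (n x 3).
#' @param n target number of points (default 1000, the size at which segment
#'   clouds are analysed).
#' @param seed integer seed (NULL = current RNG stream).
#' @return Numeric matrix with at most `n` rows.
#' @export
subsample_points <- function(points, n = 1000L, seed = NULL) {
  stopifnot(n > 0)
  points <- as.matrix(points)
  if (nrow(points) <= n) return(points)
  idx <- with_seed(seed, sample.int(nrow(points), n))
  points[idx, , drop = FALSE]
}

#' Vietoris-Rips persistence diagram of a point cloud
#'
#' Computes dimension-0 and dimension-1 persistent homology of the Rips
#' filtration in which an edge enters at the Euclidean distance between its
#' endpoints (filtration units = micrometres). Dimension-0 finite deaths equal
#' the single-linkage merge heights (MST edge lengths) and births are 0; one
#' essential dimension-0 class always remains. `max_filtration` defaults to the
#' cloud's enclosing radius (the smallest `t` at which some point is within
#' `t` of every other), at which the Rips complex is a cone and hence
#' contractible, so the finite part of the diagram is complete.
#'
#' @param points numeric matrix (n x 3), n >= 2.
#' @param max_dim 0 or 1 (loops beyond dimension 1 are not computed).
#' @param max_filtration filtration cut-off in micrometres, or `NULL` for the
#'   enclosing radius.
#' @return A tibble of class `persistence_diagram` with columns `dimension`,
#'   `birth`, `death` (finite intervals only; zero-persistence pairs dropped),
#'   and attributes `n_essential_h0`, `n_essential_h1`, `max_filtration`,
#'   `n_points`.
#' @export
rips_persistence <- function(points, max_dim = 1L, max_filtration = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 2L) stop("degenerate input: need at least 2 points")
  stopifnot(max_dim %in% c(0L, 1L))
  if (is.null(max_filtration)) {
    dm <- as.matrix(stats::dist(points))
    max_filtration <- min(apply(dm, 1L, max))
  }
  res <- rips_pairs_cpp(points, max_filtration, max_dim >= 1L)
  d0 <- res$h0_deaths[res$h0_deaths > 0]
  keep1 <- res$h1_deaths > res$h1_births
  diagram <- tibble::tibble(
    dimension = c(rep(0L, length(d0)), rep(1L, sum(keep1))),
    birth = c(rep(0, length(d0)), res$h1_births[keep1]),
    death = c(d0, res$h1_deaths[keep1]))
  structure(diagram,
            class = c("persistence_diagram", class(diagram)),
            n_essential_h0 = res$n_h0_essential,
            n_essential_h1 = res$n_h1_essential,
            max_filtration = max_filtration,
            n_points = nrow(points))
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram> %d points: %d H0 bars, %d H1 bars (+%d essential H0)\n",
              attr(x, "n_points"), sum(x$dimension == 0L),
              sum(x$dimension == 1L), attr(x, "n_essential_h0")))
  NextMethod()
}

finite_bars <- function(diagram, dimension) {
  rows <- diagram$dimension == dimension & is.finite(diagram$death)
  cbind(birth = diagram$birth[rows], death = diagram$death[rows])
}

#' Count of short bars
#'
#' Number of finite intervals in dimension `dimension` with persistence
#' (death - birth) in `(lo, hi]`; the default window (0, 10] um counts the
#' short bars that track local geometry.
#'
#' @param diagram a [rips_persistence()] diagram.
#' @param dimension homology dimension (0 or 1).
#' @param lo,hi persistence window bounds (um), lower exclusive, upper
#'   inclusive.
#' @return Integer count.
#' @export
short_bars <- function(diagram, dimension, lo = 0, hi = 10) {
  b <- finite_bars(diagram, dimension)
  len <- b[, "death"] - b[, "birth"]
  sum(len > lo & len <= hi)
}

#' Persistent entropy of a diagram
#'
#' For finite intervals with lengths `l_i` and `p_i = l_i / sum(l_i)`, returns
#' the Shannon entropy `-sum(p_i log p_i)` (natural log). Infinite-death
#' intervals are excluded. With `shannon = FALSE` the raw signed sum
#' `sum(p_i log p_i)` (which is non-positive) is returned instead.
#'
#' @inheritParams short_bars
#' @param shannon return the (non-negative) Shannon form.
#' @return Entropy in nats.
#' @export
persistent_entropy <- function(diagram, dimension, shannon = TRUE) {
  b <- finite_bars(diagram, dimension)
  len <- b[, "death"] - b[, "birth"]
  len <- len[len > 0]
  if (length(len) == 0L) {
    stop("undefined-entropy error: no finite positive-length intervals")
  }
  p <- len / sum(len)
  h <- -sum(p * log(p))
  if (shannon) h else -h
}

# first persistence landscape layer sampled on a uniform grid
landscape_lambda1 <- function(bars, grid_size) {
  if (nrow(bars) == 0L) return(list(t = numeric(0), y = numeric(0)))
  t <- seq(min(bars[, "birth"]), max(bars[, "death"]), length.out = grid_size)
  y <- numeric(grid_size)
  for (i in seq_len(nrow(bars))) {
    g <- pmax(0, pmin(t - bars[i, "birth"], bars[i, "death"] - t))
    y <- pmax(y, g)
  }
  list(t = t, y = y)
}

#' Landscape amplitude (L2 norm of the first landscape layer)
#'
#' The first persistence landscape `lambda_1(t) = max_i g_i(t)` (tent
#' functions `g_(b,d)`) is sampled on a uniform grid over the diagram's
#' filtration range and its L2 norm computed by trapezoidal integration.
#' Empty diagrams give 0.
#'
#' @inheritParams short_bars
#' @param grid_size number of grid samples.
#' @return Non-negative scalar (um^(3/2) scale).
#' @export
landscape_amplitude <- function(diagram, dimension, grid_size = 1000L) {
  b <- finite_bars(diagram, dimension)
  if (nrow(b) == 0L) return(0)
  ls <- landscape_lambda1(b, grid_size)
  y2 <- ls$y^2
  dt <- diff(ls$t)
  sqrt(sum((y2[-1] + y2[-length(y2)]) / 2 * dt))
}

#' Persistence-image amplitude (L2 norm of the raster)
#'
#' The diagram is mapped to birth-persistence coordinates, each point smoothed
#' with a Gaussian kernel weighted linearly by persistence, rasterised on a
#' `resolution x resolution` grid spanning the diagram's value range, and the
#' L2 norm of the flattened raster returned. Empty diagrams give 0.
#'
#' @inheritParams short_bars
#' @param resolution raster grid size per axis.
#' @param bandwidth Gaussian sd in filtration units; default 0.1 x the
#'   diagram's filtration range in that dimension.
#' @return Non-negative scalar.
#' @export
image_amplitude <- function(diagram, dimension, resolution = 100L,
                            bandwidth = NULL) {
  b <- finite_bars(diagram, dimension)
  if (nrow(b) == 0L) return(0)
  births <- b[, "birth"]
  pers <- b[, "death"] - b[, "birth"]
  rng <- max(b[, "death"]) - min(births)
  sigma <- bandwidth %||% max(0.1 * rng, 1e-9)
  axis_range <- function(v) {
    r <- range(v)
    if (diff(r) < 1e-12) r + c(-sigma, sigma) else r
  }
  rx <- axis_range(births)
  ry <- axis_range(pers)
  gx <- seq(rx[1], rx[2], length.out = resolution)
  gy <- seq(ry[1], ry[2], length.out = resolution)
  kx <- exp(-outer(gx, births, `-`)^2 / (2 * sigma^2))   # res x npts
  ky <- exp(-outer(gy, pers, `-`)^2 / (2 * sigma^2))
  raster <- kx %*% (t(ky) * pers) / (2 * pi * sigma^2)
  sqrt(sum(raster^2))
}

#' Wasserstein amplitude of order p
#'
#' `A_w = (sqrt(2)/2) * (sum_i (d_i - b_i)^p)^(1/p)` over finite intervals --
#' the Lp norm of the vector of point distances to the diagonal. Empty
#' diagrams give 0.
#'
#' @inheritParams short_bars
#' @param p order (default 2).
#' @return Non-negative scalar (um).
#' @export
wasserstein_amplitude <- function(diagram, dimension, p = 2) {
  b <- finite_bars(diagram, dimension)
  if (nrow(b) == 0L) return(0)
  len <- b[, "death"] - b[, "birth"]
  (sqrt(2) / 2) * sum(len^p)^(1 / p)
}

#' Bottleneck amplitude
#'
#' `A_B = (sqrt(2)/2) * max_i (d_i - b_i)` -- the Wasserstein amplitude with
#' `p -> Inf`, i.e. a fraction of the longest bar. Empty diagrams give 0.
#'
#' @inheritParams short_bars
#' @return Non-negative scalar (um).
#' @export
bottleneck_amplitude <- function(diagram, dimension) {
  b <- finite_bars(diagram, dimension)
  if (nrow(b) == 0L) return(0)
  (sqrt(2) / 2) * max(b[, "death"] - b[, "birth"])
}

entropy_or_zero <- function(diagram, dimension) {
  tryCatch(persistent_entropy(diagram, dimension), error = function(e) 0)
}

#' The 12 topological features of a point cloud
#'
#' Subsamples the cloud ([subsample_points()]), computes the Rips diagram
#' ([rips_persistence()]) and returns the twelve one-number summaries in fixed
#' column order: short-bar counts, persistent entropies, and landscape /
#' image / Wasserstein / bottleneck amplitudes, each in homology dimensions 0
#' and 1. Dimensions with no finite bars contribute 0.
#'
#' @param points numeric matrix (n x 3) with n >= 2, or a [tri_mesh()] /
#'   `papilla_segment` whose (patch) vertices are used.
#' @param n subsample size (see [subsample_points()]).
#' @param seed integer seed for the subsample.
#' @param max_filtration passed to [rips_persistence()].
#' @param grid_size landscape grid (see [landscape_amplitude()]).
#' @param image_resolution,image_bandwidth persistence-image parameters.
#' @return One-row tibble with columns `short_bars_h0`, `short_bars_h1`,
#'   `entropy_h0`, `entropy_h1`, `amp_landscape_h0/h1`, `amp_image_h0/h1`,
#'   `amp_wasserstein_h0/h1`, `amp_bottleneck_h0/h1`.
#' @export
topo_features <- function(points, n = 1000L, seed = NULL,
                          max_filtration = NULL, grid_size = 1000L,
                          image_resolution = 100L, image_bandwidth = NULL) {
  if (inherits(points, "papilla_segment")) points <- points$patch$vertices
  if (inherits(points, "tri_mesh")) points <- points$vertices
  pts <- subsample_points(points, n = n, seed = seed)
  dg <- rips_persistence(pts, max_dim = 1L, max_filtration = max_filtration)
  tibble::tibble(
    short_bars_h0 = short_bars(dg, 0L),
    short_bars_h1 = short_bars(dg, 1L),
    entropy_h0 = entropy_or_zero(dg, 0L),
    entropy_h1 = entropy_or_zero(dg, 1L),
    amp_landscape_h0 = landscape_amplitude(dg, 0L, grid_size),
    amp_landscape_h1 = landscape_amplitude(dg, 1L, grid_size),
    amp_image_h0 = image_amplitude(dg, 0L, image_resolution, image_bandwidth),
    amp_image_h1 = image_amplitude(dg, 1L, image_resolution, image_bandwidth),
    amp_wasserstein_h0 = wasserstein_amplitude(dg, 0L),
    amp_wasserstein_h1 = wasserstein_amplitude(dg, 1L),
    amp_bottleneck_h0 = bottleneck_amplitude(dg, 0L),
    amp_bottleneck_h1 = bottleneck_amplitude(dg, 1L))
}
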