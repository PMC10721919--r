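#' Points within a closed ball
#'
#' Returns the indices of all points whose 3D Euclidean distance (in the
#' ambient space) from `center` is at most `radius` -- a closed ball, so
#' boundary points are included. Computed by an exhaustive vectorised scan, so
#' the result does not depend on any acceleration structure.
#'
#' @param points numeric matrix (n x 3), micrometres.
#' @param center length-3 numeric point.
#' @param radius ball radius in micrometres (>= 0).
#' @return Integer vector of row indices of `points` inside the ball.
#' @export
radius_query <- function(points, center, radius) {
  if (radius < 0) stop("radius must be non-negative")
  center <- as_point3(center, "center")
  d2 <- (points[, 1] - center[1])^2 +
        (points[, 2] - center[2])^2 +
        (points[, 3] - center[3])^2
  which(d2 <= radius^2)
}

#' Connected component of a vertex within a vertex subset
#'
#' Connectivity is over mesh edges both of whose endpoints lie in
#' `vertex_subset` (edge adjacency is the canonical notion on a reconstructed
#' mesh). Components of the subset not containing `seed_vertex` are discarded.
#'
#' @param mesh a [tri_mesh()].
#' @param vertex_subset integer vertex indices.
#' @param seed_vertex a vertex index contained in `vertex_subset`.
#' @return Sorted integer indices of the component containing `seed_vertex`.
#' @export
connected_component_of <- function(mesh, vertex_subset, seed_vertex) {
  connected_component_idx(mesh_edges(mesh), nrow(mesh$vertices),
                          vertex_subset, seed_vertex)
}

# edge-list variant so sweeps can reuse a precomputed edge set
connected_component_idx <- function(edges, n_vertices, vertex_subset, seed_vertex) {
  vertex_subset <- sort(unique(as.integer(vertex_subset)))
  if (!seed_vertex %in% vertex_subset) {
    stop("seed vertex is not in the vertex subset")
  }
  inset <- logical(n_vertices)
  inset[vertex_subset] <- TRUE
  pos <- integer(n_vertices)
  pos[vertex_subset] <- seq_along(vertex_subset)
  keep <- inset[edges[, 1]] & inset[edges[, 2]]
  g <- igraph::make_graph(
    edges = rbind(pos[edges[keep, 1]], pos[edges[keep, 2]]),
    n = length(vertex_subset), directed = FALSE)
  memb <- igraph::components(g)$membership
  vertex_subset[memb == memb[pos[seed_vertex]]]
}

#' RANSAC hyperparameters
#'
#' Defaults: inlier threshold 20 um (well below papilla heights, so papillae
#' never dominate the base-plane fit) and 1000 random 3-point hypotheses.
#'
#' @param inlier_threshold point-to-plane distance (um) below which a point
#'   counts as an inlier.
#' @param n_iterations number of random 3-point plane hypotheses.
#' @return A list of class `ransac_params`.
#' @export
ransac_params <- function(inlier_threshold = 20, n_iterations = 1000L) {
  stopifnot(inlier_threshold > 0, n_iterations >= 1)
  structure(list(inlier_threshold = inlier_threshold,
                 n_iterations = as.integer(n_iterations)),
            class = "ransac_params")
}

#' Robust plane fit via RANSAC
#'
#' Draws `n_iterations` random 3-point hypotheses, keeps the plane with the
#' most inliers (points within `inlier_threshold` of the plane), then refits by
#' total least squares (principal plane of the inlier set). Deterministic for a
#' fixed `seed`.
#'
#' @param points numeric matrix (n x 3), at least 3 non-collinear points.
#' @param inlier_threshold inlier distance in micrometres.
#' @param n_iterations number of hypotheses.
#' @param seed integer RNG seed, or `NULL` to use the current RNG stream.
#' @return A list of class `ransac_plane` with unit `normal`, scalar `offset`
#'   (the plane is `x . normal = offset`), `inlier_threshold`, `n_inliers` and
#'   the inlier index vector.
#' @export
ransac_fit_plane <- function(points, inlier_threshold = 20,
                             n_iterations = 1000L, seed = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3L) stop("degenerate input: need at least 3 points for a plane")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2L, ctr), nu = 0L)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("degenerate input: points are (near-)collinear")
  }

  with_seed(seed, {
    idx <- matrix(0L, n_iterations, 3L)
    for (k in 1:3) idx[, k] <- sample.int(n, n_iterations, replace = TRUE)
    bad <- idx[, 1] == idx[, 2] | idx[, 1] == idx[, 3] | idx[, 2] == idx[, 3]
    p1 <- points[idx[, 1], , drop = FALSE]
    nrml <- cross3(points[idx[, 2], , drop = FALSE] - p1,
                   points[idx[, 3], , drop = FALSE] - p1)
    len <- row_norms(nrml)
    bad <- bad | len < 1e-12
    len[bad] <- 1
    nrml <- nrml / len
    offs <- rowSums(nrml * p1)
    # |x.n - d| for all points x all hypotheses
    dmat <- abs(points %*% t(nrml) - rep(offs, each = n))
    counts <- colSums(dmat <= inlier_threshold)
    counts[bad] <- -1L
    best <- which.max(counts)
    if (counts[best] < 3L) stop("degenerate input: RANSAC found no valid plane")
    inliers <- which(dmat[, best] <= inlier_threshold)
  })

  # least-squares refit on the winning inlier set
  ip <- points[inliers, , drop = FALSE]
  ctr <- colMeans(ip)
  sv <- svd(sweep(ip, 2L, ctr), nu = 0L)
  normal <- sv$v[, 3L]
  normal <- normal / sqrt(sum(normal^2))
  offset <- sum(normal * ctr)
  resid <- abs(points %*% normal - offset)
  inliers <- which(resid <= inlier_threshold)
  structure(list(normal = as.numeric(normal), offset = as.numeric(offset),
                 inlier_threshold = inlier_threshold,
                 n_inliers = length(inliers), inliers = inliers),
            class = "ransac_plane")
}

# signed distances of points from a ransac_plane
plane_distance <- function(plane, points) {
  as.numeric(points %*% plane$normal - plane$offset)
}

#' @export
print.ransac_plane <- function(x, ...) {
  cat(sprintf("<ransac_plane> normal (%.4f, %.4f, %.4f), offset %.2f, %d inliers @ %.1f um\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset,
              x$n_inliers, x$inlier_threshold))
  invisible(x)
}
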