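#' Triangle mesh in micrometre coordinates
#'
#' The basic surface container of the package: a list with a numeric
#' `vertices` matrix (n x 3, micrometres) and an integer `triangles` matrix
#' (m x 3, 1-based vertex indices). All downstream stages (segment extraction,
#' curvature, persistence) operate on this representation.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in micrometres).
#' @param triangles integer matrix with 3 columns of 1-based vertex indices,
#'   or `NULL` for a bare point cloud (0 triangles).
#' @param validate check mesh invariants (valid indices, no degenerate or
#'   duplicate triangles).
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, triangles = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(vertices) == 0L) stop("empty vertex set")
  if (is.null(triangles)) {
    triangles <- matrix(integer(0), ncol = 3L)
  } else {
    triangles <- as.matrix(triangles)
    storage.mode(triangles) <- "integer"
    if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  }
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  mesh <- structure(list(vertices = vertices, triangles = triangles),
                    class = "tri_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate triangle mesh invariants
#'
#' Checks that all triangle indices reference existing vertices, that no
#' triangle repeats a vertex, and that no triangle appears twice.
#'
#' @param mesh a [tri_mesh()].
#' @return The mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  if (anyNA(v) || any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v)) {
      stop("triangle references a vertex index outside 1..", nrow(v))
    }
    if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3])) {
      stop("degenerate triangle repeats a vertex")
    }
    key <- apply(f, 1L, function(r) paste(sort(r), collapse = "-"))
    if (anyDuplicated(key)) stop("duplicate triangles")
  }
  invisible(mesh)
}

#' Undirected edge set of a mesh
#'
#' @param mesh a [tri_mesh()].
#' @return Integer matrix (k x 2) of unique undirected edges, each row sorted.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$triangles
  if (nrow(f) == 0L) return(matrix(integer(0), ncol = 2L))
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(1, 3), drop = FALSE],
             f[, c(2, 3), drop = FALSE])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  unique(cbind(lo, hi, deparse.level = 0))
}

#' Boundary vertices of a mesh
#'
#' A vertex is on the boundary when it belongs to an edge used by exactly one
#' triangle. Closed meshes have none.
#'
#' @param mesh a [tri_mesh()].
#' @return Integer vertex indices, sorted.
#' @export
boundary_vertices <- function(mesh) {
  f <- mesh$triangles
  n <- nrow(mesh$vertices)
  if (nrow(f) == 0L) return(seq_len(n))
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(1, 3), drop = FALSE],
             f[, c(2, 3), drop = FALSE])
  key <- pmin(e[, 1], e[, 2]) * (n + 1) + pmax(e[, 1], e[, 2])
  cnt <- table(key)
  single <- as.numeric(names(cnt)[cnt == 1L])
  if (length(single) == 0L) return(integer(0))
  sort(unique(c(single %/% (n + 1), single %% (n + 1))))
}

#' Area-weighted vertex normals
#'
#' Normals follow the triangle winding; vertices incident to no triangle fall
#' back to +z (synthetic surfaces are z-up heightfields).
#'
#' @param mesh a [tri_mesh()].
#' @return Numeric matrix (n x 3) of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  n <- nrow(v)
  out <- matrix(0, n, 3L)
  if (nrow(f) > 0L) {
    a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    fn <- cross3(a, b)  # magnitude = 2 * area
    for (c_i in 1:3) {
      for (dim in 1:3) {
        out[, dim] <- out[, dim] + accumulate_at(f[, c_i], fn[, dim], n)
      }
    }
  }
  nrm <- row_norms(out)
  zero <- nrm < 1e-12
  out[zero, ] <- matrix(rep(c(0, 0, 1), each = sum(zero)), ncol = 3L)
  nrm[zero] <- 1
  out / nrm
}

#' @export
print.tri_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("<tri_mesh> %d vertices, %d triangles, %d edges\n",
              nrow(x$vertices), nrow(x$triangles), nrow(mesh_edges(x))))
  cat(sprintf("  bbox [um]: x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Submesh induced by a vertex subset
#'
#' Keeps the triangles all of whose corners lie in `vertex_idx` and re-indexes
#' them against the retained vertices.
#'
#' @param mesh a [tri_mesh()].
#' @param vertex_idx integer vertex indices to keep.
#' @return A [tri_mesh()].
#' @export
submesh <- function(mesh, vertex_idx) {
  vertex_idx <- sort(unique(as.integer(vertex_idx)))
  pos <- integer(nrow(mesh$vertices))
  pos[vertex_idx] <- seq_along(vertex_idx)
  f <- mesh$triangles
  keep <- pos[f[, 1]] > 0L & pos[f[, 2]] > 0L & pos[f[, 3]] > 0L
  tri <- matrix(pos[f[keep, , drop = FALSE]], ncol = 3L)
  tri_mesh(mesh$vertices[vertex_idx, , drop = FALSE], tri, validate = FALSE)
}
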