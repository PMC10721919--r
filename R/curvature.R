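# Discrete differential geometry on triangle meshes, following the mixed
# finite-element/finite-volume discretisation of Meyer, Desbrun, Schroeder &
# Barr: Gaussian curvature is the vertex angle deficit normalised by the mixed
# Voronoi area; mean curvature comes from the cotangent Laplace-Beltrami
# vector, signed by the outward vertex normal.

#' Per-vertex discrete curvatures
#'
#' Gaussian curvature at an interior vertex is
#' `(2*pi - sum of incident triangle angles) / A_mixed`, where `A_mixed` is the
#' mixed Voronoi area (Voronoi cell area for non-obtuse triangles; area/2 at
#' the obtuse corner and area/4 elsewhere for obtuse ones). Mean curvature is
#' half the norm of the cotangent-weighted Laplace vector divided by
#' `A_mixed`, signed positive where the surface bends toward its outward
#' normal (convex bumps). Boundary vertices are flagged and excluded from all
#' downstream curvature statistics.
#'
#' @param mesh a [tri_mesh()] with at least one interior vertex.
#' @return A tibble with one row per vertex: `vertex`, `gaussian` (um^-2),
#'   `mean` (um^-1, signed), `angle_defect` (rad), `area_mixed` (um^2),
#'   `boundary` (logical). Curvatures are `NA` on the boundary.
#' @export
discrete_curvatures <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  n <- nrow(v)
  if (nrow(f) == 0L) stop("empty-field error: mesh has no triangles")

  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  e12 <- v[i2, , drop = FALSE] - v[i1, , drop = FALSE]
  e13 <- v[i3, , drop = FALSE] - v[i1, , drop = FALSE]
  e23 <- v[i3, , drop = FALSE] - v[i2, , drop = FALSE]

  cr <- cross3(e12, e13)
  area2 <- row_norms(cr)            # 2 * triangle area
  area <- area2 / 2

  dot1 <- rowSums(e12 * e13)        # corner at i1
  dot2 <- rowSums(-e12 * e23)       # corner at i2
  dot3 <- rowSums(e13 * e23)        # corner at i3 (between -e13 and -e23)
  ang1 <- atan2(area2, dot1)
  ang2 <- atan2(area2, dot2)
  ang3 <- atan2(area2, dot3)
  cot1 <- dot1 / area2
  cot2 <- dot2 / area2
  cot3 <- dot3 / area2

  angle_sum <- accumulate_at(i1, ang1, n) + accumulate_at(i2, ang2, n) +
    accumulate_at(i3, ang3, n)

  # mixed Voronoi areas
  l12 <- rowSums(e12^2); l13 <- rowSums(e13^2); l23 <- rowSums(e23^2)
  obtuse1 <- dot1 < 0; obtuse2 <- dot2 < 0; obtuse3 <- dot3 < 0
  any_obtuse <- obtuse1 | obtuse2 | obtuse3
  a1 <- ifelse(any_obtuse, ifelse(obtuse1, area / 2, area / 4),
               (l12 * cot3 + l13 * cot2) / 8)
  a2 <- ifelse(any_obtuse, ifelse(obtuse2, area / 2, area / 4),
               (l12 * cot3 + l23 * cot1) / 8)
  a3 <- ifelse(any_obtuse, ifelse(obtuse3, area / 2, area / 4),
               (l13 * cot2 + l23 * cot1) / 8)
  area_mixed <- accumulate_at(i1, a1, n) + accumulate_at(i2, a2, n) +
    accumulate_at(i3, a3, n)

  # cotangent Laplace vector: for edge (a, b) opposite corner c, cot_c*(x_a-x_b)
  lap <- matrix(0, n, 3L)
  add_edge <- function(lap, a, b, w, ea_b) {
    for (dim in 1:3) {
      lap[, dim] <- lap[, dim] + accumulate_at(a, w * ea_b[, dim], n)
      lap[, dim] <- lap[, dim] + accumulate_at(b, -w * ea_b[, dim], n)
    }
    lap
  }
  lap <- add_edge(lap, i1, i2, cot3, -e12)   # x1 - x2
  lap <- add_edge(lap, i1, i3, cot2, -e13)   # x1 - x3
  lap <- add_edge(lap, i2, i3, cot1, -e23)   # x2 - x3

  bnd <- logical(n)
  bnd[boundary_vertices(mesh)] <- TRUE
  interior <- !bnd & area_mixed > 0
  if (!any(interior)) stop("empty-field error: all vertices lie on the boundary")

  defect <- 2 * pi - angle_sum
  gaussian <- ifelse(interior, defect / area_mixed, NA_real_)

  nrm <- vertex_normals(mesh)
  hvec <- lap / pmax(2 * area_mixed, 1e-300)
  h_mag <- row_norms(hvec) / 2
  h_sign <- sign(rowSums(hvec * nrm))
  h_sign[h_sign == 0] <- 1
  mean_curv <- ifelse(interior, h_sign * h_mag, NA_real_)

  tibble::tibble(vertex = seq_len(n), gaussian = gaussian, mean = mean_curv,
                 angle_defect = defect, area_mixed = area_mixed,
                 boundary = bnd)
}

#' Curvature summary features of a segment
#'
#' Aggregates a [discrete_curvatures()] field over interior vertices into the
#' curvature feature family: extrema of Gaussian and mean curvature, the
#' counts `x` (Gaussian curvature > 0) and `y` (< 0), the curvature ratio
#' `k_ratio = y/x` if `y <= x` else `x/y`, and the positive ratio
#' `k_positiveratio = x/(x + y)`. Zero-curvature vertices count in neither `x`
#' nor `y`.
#'
#' @param field a tibble from [discrete_curvatures()].
#' @return A one-row tibble: `gauss_max`, `gauss_min`, `mean_max`, `mean_min`,
#'   `k_ratio`, `k_positiveratio`, `n_positive`, `n_negative`.
#' @export
curvature_summary <- function(field) {
  k <- field$gaussian[!field$boundary & !is.na(field$gaussian)]
  h <- field$mean[!field$boundary & !is.na(field$mean)]
  if (length(k) == 0L) stop("empty-field error: no interior curvature values")
  x <- sum(k > 0)
  y <- sum(k < 0)
  if (x + y == 0L) stop("undefined-ratio error: no vertex with nonzero curvature sign")
  tibble::tibble(
    gauss_max = max(k), gauss_min = min(k),
    mean_max = max(h), mean_min = min(h),
    k_ratio = min(x, y) / max(x, y),
    k_positiveratio = x / (x + y),
    n_positive = x, n_negative = y)
}
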