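# Candidate papilla segment extraction: around a random surface point P, take
# the connected set B of points within r + delta, fit the base plane by RANSAC,
# take the point M furthest above the plane as the local maximum, re-centre on
# M and repeat until M is a fixed point, then cut the radius-r patch around M.
# A whole-surface sweep repeats this, ignoring any maximum that falls inside a
# previously accepted segment.

#' Default segment cut radius
#'
#' `max(r_fungiform, r_filiform)` with r_fungiform = 439 um and
#' r_filiform = 177.5 um, the radii found to work well for automated papilla
#' detection; the margin `delta` (100 um) fully covers any papilla near the
#' seed point.
#' @return Numeric scalar, micrometres.
#' @export
segment_radius <- function() max(439, 177.5)

#' Extract one candidate papilla segment
#'
#' Steps, in order: (1) collect vertices within `r + delta` of the seed point
#' P (closed ball, ambient 3D distance); (2) keep only the mesh-edge-connected
#' component containing P; (3) fit the base plane to that component by RANSAC,
#' with the normal oriented toward the component's mean outward vertex normal
#' so "furthest" means highest above the base; (4) let M be the component
#' vertex with maximum signed plane distance within `recenter_window` of the
#' current centre, then repeat the windowed maximisation centred on M until M
#' stops moving uphill (bounded at `max_recenter` rounds), so that M is a
#' genuine local maximum of the surface -- the walk measures height against
#' the seed component's plane, and the plane is refit once on the final
#' component; (5) cut the patch of vertices within `r` of M (induced
#' triangles, component of M).
#'
#' The windowed uphill walk in step (4) matters in two ways. Unwindowed, a
#' seed landing just beyond `r + delta` of a papilla apex claims a flank
#' point as its "maximum" (the apex is outside the seed's ball) and then
#' permanently suppresses the true apex during a sweep; the walk instead
#' climbs the flank to the apex. The window, in turn, must exceed the
#' apex-to-spike-tip offset of crown-shaped papillae (~110 um) so spike tips
#' escape to the central apex, yet stay below the closest approach of a
#' taller neighbouring papilla's higher flank (>= ~370 um when base disks are
#' disjoint) so the walk can never cross the valley between two papillae.
#'
#' @param mesh a [tri_mesh()].
#' @param seed_vertex vertex index of the seed point P.
#' @param r cut radius (um), see [segment_radius()].
#' @param delta margin (um) added around P so any papilla is fully covered.
#' @param ransac a [ransac_params()].
#' @param recenter_window radius (um) of the uphill re-centring window of
#'   step (4).
#' @param max_recenter cap on the re-centring rounds of step (4).
#' @param seed RNG seed for the RANSAC draws (NULL = current stream).
#' @param edges,normals optional precomputed [mesh_edges()] /
#'   [vertex_normals()] (used by [sweep_surface()] to avoid recomputation).
#' @return A `papilla_segment`: list with `patch` (submesh), global
#'   `patch_vertices`, seed point `P`, `base_plane`, local maximum `M` (+ its
#'   global vertex index and height above the plane), `r`, `delta`, `label`
#'   and `metadata`.
#' @export
extract_segment <- function(mesh, seed_vertex, r = segment_radius(),
                            delta = 100, ransac = ransac_params(),
                            recenter_window = 250, max_recenter = 20L,
                            seed = NULL, edges = NULL, normals = NULL) {
  stopifnot(r > 0, delta > 0, recenter_window > 0, max_recenter >= 1L)
  v <- mesh$vertices
  n <- nrow(v)
  if (seed_vertex < 1L || seed_vertex > n) stop("seed vertex out of range")
  edges <- edges %||% mesh_edges(mesh)
  normals <- normals %||% vertex_normals(mesh)
  p <- v[seed_vertex, ]

  fit_base_plane <- function(comp) {
    plane <- ransac_fit_plane(v[comp, , drop = FALSE],
                              inlier_threshold = ransac$inlier_threshold,
                              n_iterations = ransac$n_iterations, seed = seed)
    outward <- colMeans(normals[comp, , drop = FALSE])
    if (sum(plane$normal * outward) < 0) {
      plane$normal <- -plane$normal
      plane$offset <- -plane$offset
    }
    plane
  }
  component_around <- function(centre_vertex) {
    ball <- radius_query(v, v[centre_vertex, ], r + delta)
    comp <- connected_component_idx(edges, n, ball, centre_vertex)
    if (length(comp) < 3L) stop("degenerate input: component has < 3 points")
    comp
  }

  # the uphill walk measures height against the seed component's plane; the
  # plane is refit once on the final component so the stored base_plane and
  # M_height belong to M's own neighbourhood
  centre_vertex <- seed_vertex
  comp <- component_around(centre_vertex)
  plane <- fit_base_plane(comp)
  for (round in seq_len(max_recenter)) {
    centre <- v[centre_vertex, ]
    sdist <- plane_distance(plane, v[comp, , drop = FALSE])
    near <- row_norms(v[comp, , drop = FALSE] -
                        matrix(centre, length(comp), 3L, byrow = TRUE)) <=
      recenter_window
    best <- comp[near][which.max(sdist[near])]
    # move only strictly uphill: ties (e.g. an exactly flat sheet) stay put
    if (best == centre_vertex ||
        sdist[match(best, comp)] <= sdist[match(centre_vertex, comp)] + 1e-9) {
      break
    }
    centre_vertex <- best
    comp <- component_around(centre_vertex)
  }
  m_vertex <- centre_vertex
  if (m_vertex != seed_vertex) plane <- fit_base_plane(comp)
  m_height <- plane_distance(plane, rbind(v[m_vertex, ]))[1]
  m <- v[m_vertex, ]

  patch_ball <- radius_query(v, m, r)
  patch_idx <- connected_component_idx(edges, n, patch_ball, m_vertex)
  patch <- submesh(mesh, patch_idx)

  structure(list(patch = patch, patch_vertices = patch_idx,
                 seed_vertex = seed_vertex, P = p,
                 base_plane = plane, M = m, M_vertex = m_vertex,
                 M_height = m_height, r = r, delta = delta,
                 label = "unlabelled", metadata = list()),
            class = "papilla_segment")
}

#' @export
print.papilla_segment <- function(x, ...) {
  cat(sprintf("<papilla_segment> %s | %d patch vertices, r = %.1f um, M height %.1f um\n",
              x$label, nrow(x$patch$vertices), x$r, x$M_height))
  invisible(x)
}

#' Sweep a surface for candidate papilla segments
#'
#' Repeatedly picks random unprocessed seed vertices, extracts a segment
#' around each ([extract_segment()]), and suppresses any new local maximum
#' falling within `suppress_r` of a previously accepted maximum. Seeds inside
#' already-accepted segments are skipped. The sweep stops when the seed pool
#' is exhausted, after `max_iterations` extraction attempts, or after
#' `stop_after` consecutive attempts yield no new maximum. Deterministic given
#' `seed`; degenerate plane fits are skipped with a warning.
#'
#' @inheritParams extract_segment
#' @param max_iterations cap on extraction attempts.
#' @param stop_after consecutive no-new-maximum attempts before stopping.
#' @param suppress_r suppression radius around accepted maxima (defaults to
#'   `r`).
#' @param seed integer seed.
#' @return List of `papilla_segment` objects (class `segment_sweep`), with the
#'   accepted maxima pairwise more than `suppress_r` apart.
#' @export
sweep_surface <- function(mesh, r = segment_radius(), delta = 100,
                          max_iterations = 5000L, stop_after = 100L,
                          suppress_r = r, ransac = ransac_params(), seed = 1) {
  v <- mesh$vertices
  n <- nrow(v)
  edges <- mesh_edges(mesh)
  normals <- vertex_normals(mesh)
  order <- with_seed(seed, sample.int(n))

  visited <- logical(n)
  segments <- list()
  m_pts <- matrix(numeric(0), 0L, 3L)
  attempts <- 0L
  fails <- 0L
  for (p in order) {
    if (visited[p]) next
    if (attempts >= max_iterations || fails >= stop_after) break
    attempts <- attempts + 1L
    visited[p] <- TRUE
    seg <- tryCatch(
      extract_segment(mesh, p, r = r, delta = delta, ransac = ransac,
                      seed = derive_seed(seed, p), edges = edges,
                      normals = normals),
      error = function(e) {
        warning("segment at vertex ", p, " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(seg)) next
    if (nrow(m_pts) > 0L) {
      d <- sqrt((m_pts[, 1] - seg$M[1])^2 + (m_pts[, 2] - seg$M[2])^2 +
                  (m_pts[, 3] - seg$M[3])^2)
      if (any(d <= suppress_r)) {
        fails <- fails + 1L
        next
      }
    }
    fails <- 0L
    segments[[length(segments) + 1L]] <- seg
    m_pts <- rbind(m_pts, seg$M)
    visited[radius_query(v, seg$M, suppress_r)] <- TRUE
  }
  structure(segments, class = c("segment_sweep", "list"),
            r = r, delta = delta, seed = seed, attempts = attempts)
}

#' @export
print.segment_sweep <- function(x, ...) {
  cat(sprintf("<segment_sweep> %d segments (r = %.1f um, %d attempts)\n",
              length(x), attr(x, "r"), attr(x, "attempts")))
  invisible(x)
}

#' Label swept segments against planted ground truth
#'
#' A segment takes the type of the planted papilla whose base disk contains
#' its local maximum M (in xy); otherwise it is labelled `"none"`. Participant
#' metadata from the surface is attached.
#'
#' @param segments a list of `papilla_segment`s (e.g. a [sweep_surface()]
#'   result).
#' @param surface the `annotated_surface` they were extracted from.
#' @return The segments with `label` and `metadata` filled in.
#' @export
label_segments <- function(segments, surface) {
  pap <- surface$papillae
  prof <- surface$participant
  meta <- list(
    participant = prof$participant_id %||% NA_character_,
    gender = prof$gender %||% NA_character_,
    age = prof$age %||% NA_real_,
    age_group = if (!is.null(prof$age)) {
      if (prof$age <= 28) "young" else "old"
    } else NA_character_)
  out <- lapply(segments, function(seg) {
    lab <- "none"
    if (nrow(pap) > 0L) {
      d <- sqrt((pap$x - seg$M[1])^2 + (pap$y - seg$M[2])^2)
      j <- which.min(d)
      if (d[j] <= pap$base_radius[j]) lab <- pap$type[j]
    }
    seg$label <- lab
    seg$metadata <- meta
    seg
  })
  attributes(out) <- attributes(segments)
  out
}
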