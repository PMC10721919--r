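# Baseline shape measurements: the radius of the sphere around the local
# maximum containing 90% of the segment's points, grown iteratively from
# 100 um in 10 um steps, and the height of the local maximum above a RANSAC
# base plane fitted to the radius-limited region.

#' Segment radius: 90% containment sphere around M
#'
#' Mimics the manual procedure: start with a guess of 100 um, count the points
#' within that distance of M, and grow the radius by 10 um until the count
#' reaches 90% of all points; the stopping value is the radius. The result is
#' therefore quantised to the grid 100, 110, 120, ... um and never below
#' 100 um.
#'
#' @param points numeric matrix (n x 3) of segment points.
#' @param m the local maximum point (length-3).
#' @param start,step initial radius and increment (um).
#' @param coverage required fraction of contained points.
#' @return Radius in micrometres.
#' @export
compute_radius <- function(points, m, start = 100, step = 10, coverage = 0.9) {
  m <- as_point3(m, "m")
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 1L) stop("need at least one point")
  d <- sqrt((points[, 1] - m[1])^2 + (points[, 2] - m[2])^2 +
              (points[, 3] - m[3])^2)
  k <- ceiling(coverage * n - 1e-9)  # smallest count >= coverage * n
  dk <- sort(d)[k]
  if (dk <= start) start else start + step * ceiling((dk - start) / step)
}

#' Segment height: distance from M to the RANSAC base plane
#'
#' Cuts the region of radius `r_seg` around M, fits a plane to it with RANSAC,
#' and returns the unsigned distance from the plane to M.
#'
#' @param points numeric matrix (n x 3) of segment points.
#' @param m the local maximum point.
#' @param r_seg region radius (um), typically from [compute_radius()].
#' @param ransac a [ransac_params()].
#' @param seed RNG seed for RANSAC.
#' @return Height in micrometres (>= 0).
#' @export
compute_height <- function(points, m, r_seg, ransac = ransac_params(),
                           seed = NULL) {
  m <- as_point3(m, "m")
  points <- as.matrix(points)
  idx <- radius_query(points, m, r_seg)
  if (length(idx) < 3L) stop("degenerate input: < 3 points within r_seg of M")
  plane <- ransac_fit_plane(points[idx, , drop = FALSE],
                            inlier_threshold = ransac$inlier_threshold,
                            n_iterations = ransac$n_iterations, seed = seed)
  abs(sum(m * plane$normal) - plane$offset)
}

#' Baseline + curvature features of one segment
#'
#' The radius is the 90%-containment sphere of the patch points around M
#' ([compute_radius()]). The height is the unsigned distance from M to the
#' segment's base plane: the plane fitted by RANSAC over the full
#' extraction neighbourhood (the `r + delta` ball) during
#' [extract_segment()]. The patch itself (the `r`-ball around M) excludes
#' the surrounding base surface for tall papillae, so refitting a plane to
#' the patch alone would track the papilla flank rather than the base; the
#' extraction plane is the one that sees the base.
#'
#' @param segment a `papilla_segment`.
#' @param ransac a [ransac_params()]; used only when the segment lacks a
#'   stored base plane, in which case [compute_height()] is applied to the
#'   patch points.
#' @param seed RNG seed for the fallback plane fit.
#' @return One-row tibble: `height_um`, `radius_um`, and the
#'   [curvature_summary()] columns.
#' @export
geometry_features <- function(segment, ransac = ransac_params(), seed = NULL) {
  pts <- segment$patch$vertices
  r_seg <- compute_radius(pts, segment$M)
  if (!is.null(segment$base_plane)) {
    h <- abs(plane_distance(segment$base_plane, rbind(segment$M)))
  } else {
    h <- compute_height(pts, segment$M, r_seg, ransac = ransac, seed = seed)
  }
  curv <- curvature_summary(discrete_curvatures(segment$patch))
  dplyr::bind_cols(tibble::tibble(height_um = h, radius_um = r_seg),
                   curv[, c("gauss_max", "gauss_min", "mean_max", "mean_min",
                            "k_ratio", "k_positiveratio")])
}
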