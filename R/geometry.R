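# Thickness geometry: reference plane from three marker-ball centers,
# minimum calcaneus-to-plane distance, contact detection, primary thickness.
# All lengths in mm.

#' Reference plane through three marker-ball centers
#'
#' The force-plate reference plane is defined by the centers of three steel
#' balls resting on the plate; because each ball touches the plate, the plane
#' through the centers is parallel to the plate at a height of one ball
#' radius. The normal is oriented from the plate toward the foot.
#'
#' @param centers 3 x 3 numeric matrix, one ball center per row (mm).
#' @param radius ball radius (mm), > 0.
#' @param toward optional 3-vector on the foot side; when supplied the normal
#'   is oriented toward it. Otherwise the normal is oriented to have positive
#'   z component (lab frame z up), falling back to the first nonzero
#'   component.
#' @return An object of class `ref_plane`: list with `point` (3-vector) and
#'   unit `normal` (3-vector), plus the `radius` used.
#' @export
#' @examples
#' plane_from_balls(rbind(c(0, 0, 5), c(100, 0, 5), c(0, 100, 5)), radius = 5)
plane_from_balls <- function(centers, radius, toward = NULL) {
  centers <- as.matrix(centers)
  if (!is.numeric(centers) || !all(dim(centers) == c(3L, 3L)))
    stopf("'centers' must be a 3 x 3 numeric matrix (one center per row)",
          class = "degenerate_geometry_error")
  assert_number(radius, "radius", lower = 0, strict_lower = TRUE)
  v1 <- centers[2L, ] - centers[1L, ]
  v2 <- centers[3L, ] - centers[1L, ]
  n <- c(v1[2L] * v2[3L] - v1[3L] * v2[2L],
         v1[3L] * v2[1L] - v1[1L] * v2[3L],
         v1[1L] * v2[2L] - v1[2L] * v2[1L])
  nn <- sqrt(sum(n^2))
  sides <- c(sqrt(sum(v1^2)), sqrt(sum(v2^2)), sqrt(sum((v2 - v1)^2)))
  longest <- max(sides)
  # triangle area = nn/2; minimum altitude = 2 * area / longest side
  min_altitude <- if (longest > 0) nn / longest else 0
  if (longest == 0 || min_altitude < 1e-9 * max(1, longest))
    stopf(paste0("ball centers are collinear or duplicated; ",
                 "minimum triangle altitude = %.3g mm"), min_altitude,
          class = "degenerate_geometry_error")
  n <- n / nn
  if (!is.null(toward)) {
    if (sum((toward - centers[1L, ]) * n) < 0) n <- -n
  } else if (abs(n[3L]) > 1e-12) {
    if (n[3L] < 0) n <- -n
  } else {
    k <- which(abs(n) > 1e-12)[1L]
    if (n[k] < 0) n <- -n
  }
  structure(list(point = centers[1L, ], normal = n, radius = radius),
            class = "ref_plane")
}

#' Heel-pad thickness from a calcaneus point cloud
#'
#' Thickness is the minimum signed distance from the calcaneus point cloud to
#' the ball-center plane, plus the ball radius (the plane sits one radius
#' above the plate). Distances are signed along the plane normal (oriented
#' plate to foot), so points penetrating the plate produce a negative
#' contribution rather than silently inflating the minimum; the value is
#' reported, never clamped.
#'
#' @param cloud n x 3 numeric matrix of calcaneus surface points (mm).
#' @param plane a [plane_from_balls()] `ref_plane`.
#' @param radius ball radius (mm); defaults to the radius stored in `plane`.
#' @return Thickness in mm (equivalently, the minimum point height above the
#'   plate for an untilted scene).
#' @export
heel_pad_thickness <- function(cloud, plane, radius = plane$radius) {
  cloud <- as.matrix(cloud)
  if (length(cloud) == 0L || nrow(cloud) == 0L)
    stopf("point cloud is empty", class = "empty_input_error")
  if (ncol(cloud) != 3L)
    stopf("point cloud must have 3 columns (x, y, z)", class = "empty_input_error")
  assert_number(radius, "radius", lower = 0, strict_lower = TRUE)
  d <- (cloud[, 1L] - plane$point[1L]) * plane$normal[1L] +
       (cloud[, 2L] - plane$point[2L]) * plane$normal[2L] +
       (cloud[, 3L] - plane$point[3L]) * plane$normal[3L]
  min(d) + radius
}

#' First frame of sustained heel-ground contact
#'
#' Returns the first frame index `i` such that `force[i .. i+min_consecutive-1]`
#' are all at or above `threshold`. Indices are 1-based.
#'
#' @param force vertical heel-ground force series (N).
#' @param threshold contact force threshold (N), > 0.
#' @param min_consecutive number of consecutive qualifying frames required.
#' @return Frame index (1-based).
#' @export
#' @examples
#' detect_contact_frame(c(0, 0, 12, 30, 60), threshold = 10) # 3
detect_contact_frame <- function(force, threshold, min_consecutive = 1L) {
  if (length(force) == 0L) stopf("force series is empty", class = "empty_input_error")
  assert_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  assert_number(min_consecutive, "min_consecutive", lower = 1)
  ok <- force >= threshold
  n <- length(force)
  m <- as.integer(min_consecutive)
  if (n >= m) {
    run <- 0L
    for (i in seq_len(n)) {
      run <- if (ok[i]) run + 1L else 0L
      if (run >= m) return(i - m + 1L)
    }
  }
  stopf("no frame reaches the contact threshold of %g N for %d consecutive frames",
        threshold, m, class = "no_contact_error")
}

#' Onset frame of initial skin-plate contact
#'
#' Refines [detect_contact_frame()]: from the threshold crossing, walk back
#' through the contiguous run of above-baseline force to the last frame at or
#' below `baseline`. That frame is taken as the instant the heel skin first
#' touches the plate, before measurable load develops -- the frame whose
#' thickness is the primary (unloaded) thickness. This mirrors the usual
#' gait-event onset-backtracking heuristic: the threshold rejects baseline
#' noise, the walk-back removes the threshold's detection lag.
#'
#' @inheritParams detect_contact_frame
#' @param baseline force level (N) regarded as no load; default 0.
#' @return Frame index (1-based) of contact onset.
#' @export
contact_onset_frame <- function(force, threshold, min_consecutive = 1L,
                                baseline = 0) {
  i <- detect_contact_frame(force, threshold, min_consecutive)
  while (i > 1L && force[i - 1L] > baseline) i <- i - 1L
  if (i > 1L) i - 1L else i
}

#' Primary (unloaded) heel-pad thickness
#'
#' The thickness at the frame of initial heel-plate contact. Accepts either a
#' per-frame thickness channel (numeric vector or a `heel_trial` with a
#' `thickness_mm` column) or a [geometry_scene] whose per-frame clouds are
#' reduced through [heel_pad_thickness()].
#'
#' @param x numeric thickness series (mm), a `heel_trial`, or a
#'   `geometry_scene`.
#' @param contact_index frame index of contact (1-based).
#' @param plane optional `ref_plane`; computed from the scene's ball centers
#'   when `x` is a scene and `plane` is NULL.
#' @return Primary thickness in mm.
#' @export
primary_thickness <- function(x, contact_index, plane = NULL) {
  assert_number(contact_index, "contact_index", lower = 1)
  ci <- as.integer(contact_index)
  if (inherits(x, "geometry_scene")) {
    if (ci > length(x$frames))
      stopf("contact_index %d exceeds the scene's %d frames", ci,
            length(x$frames), class = "invalid_input_error")
    if (is.null(plane)) plane <- plane_from_balls(x$ball_centers, x$ball_radius)
    return(heel_pad_thickness(x$frames[[ci]]$cloud, plane, x$ball_radius))
  }
  th <- if (is.data.frame(x)) x$thickness_mm else x
  if (is.null(th) || !is.numeric(th))
    stopf("'x' must be a thickness series, heel_trial or geometry_scene",
          class = "invalid_input_error")
  if (ci > length(th))
    stopf("contact_index %d exceeds series length %d", ci, length(th),
          class = "invalid_input_error")
  th[ci]
}

#' @export
print.ref_plane <- function(x, ...) {
  cat("Force-plate reference plane\n")
  cat(sprintf("  point : (%.3f, %.3f, %.3f) mm\n",
              x$point[1], x$point[2], x$point[3]))
  cat(sprintf("  normal: (%.6f, %.6f, %.6f)\n",
              x$normal[1], x$normal[2], x$normal[3]))
  cat(sprintf("  ball radius: %.3f mm\n", x$radius))
  invisible(x)
}
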