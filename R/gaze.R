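# Head-centric gaze reconstruction: head calibration from morphological
# keypoints, pose recovery from marker rigid bodies, horizon correction,
# marker-label repair, retinal-specialization ray projection and dome
# (hypothetical sky) gaze-density maps.
#
# Conventions (documented on every angle interface):
# head frame: origin at the eye midpoint, +y toward the beak tip, +x toward
# the right eye, +z up; Euler angles are intrinsic yaw (about z), then
# pitch (about the head's x), then roll (about the head's y):
# R_head_to_world = Rz(yaw) %*% Rx(pitch) %*% Ry(roll).
# Azimuth is measured clockwise from +y (beak) toward +x (right eye);
# elevation from the horizon plane, positive up.

rotmat_from_ypr <- function(yaw, pitch, roll) {
  rot_z(yaw) %*% rot_x(pitch) %*% rot_y(roll)
}

ypr_from_rotmat <- function(R) {
  pitch <- asin(pmin(pmax(R[3, 2], -1), 1))
  yaw <- atan2(-R[1, 2], R[2, 2])
  M <- rot_x(-pitch) %*% rot_z(-yaw) %*% R      # residual Ry(roll)
  roll <- atan2(M[1, 3], M[1, 1])
  c(yaw = yaw, pitch = pitch, roll = roll)
}

# azimuth (clockwise from +y toward +x) / elevation -> unit head-frame ray
azel_to_dir <- function(az, el) {
  cbind(sin(az) * cos(el), cos(az) * cos(el), sin(el))
}

#' Calibrate the head frame from markers and morphological keypoints
#'
#' Given the head-marker coordinates and the eye centers and beak tip
#' measured in one common calibration frame, constructs the head-centric
#' frame (origin at the eye midpoint, +y toward the beak, +x toward the
#' right eye, +z up) and stores the marker template expressed in that
#' frame. Poses are later recovered by rigidly fitting this template to the
#' observed markers, so the calibration is invariant to any rigid motion of
#' all calibration inputs.
#'
#' @param markers k x 3 matrix of head-marker positions (k >= 3,
#'   non-collinear), calibration frame.
#' @param eye_left,eye_right,beak_tip 3-vectors, same frame.
#' @return object of class `head_calibration` with `marker_template` and
#'   `keypoints` in head-frame coordinates.
#' @export
calibrate_head <- function(markers, eye_left, eye_right, beak_tip) {
  markers <- as_points3(markers)
  if (nrow(markers) < 3L) stop("need at least 3 markers", call. = FALSE)
  sv <- svd(scale(markers, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12)) {
    stop("markers are collinear: head frame is unconstrained", call. = FALSE)
  }
  eye_left <- vec3(eye_left); eye_right <- vec3(eye_right)
  beak_tip <- vec3(beak_tip)
  origin <- (eye_left + eye_right) / 2
  x_axis <- unit_vec(eye_right - origin)
  b <- beak_tip - origin
  y_raw <- b - sum(b * x_axis) * x_axis
  if (sqrt(sum(y_raw^2)) < 1e-9) {
    stop("beak tip lies on the eye axis: head frame is unconstrained",
         call. = FALSE)
  }
  y_axis <- unit_vec(y_raw)
  z_axis <- cross3(x_axis, y_axis)
  Rcw <- cbind(x_axis, y_axis, z_axis)   # head axes as world columns
  to_head <- function(p) as.numeric(t(Rcw) %*% (p - origin))
  template <- t(apply(markers, 1, to_head))
  structure(list(
    marker_template = template,
    keypoints = rbind(eye_left = to_head(eye_left),
                      eye_right = to_head(eye_right),
                      beak_tip = to_head(beak_tip))),
    class = "head_calibration")
}

#' Recover head poses from marker tracks
#'
#' Fits the calibration's marker template to the observed markers of each
#' frame (least-squares rigid transform), yielding the head origin (eye
#' midpoint) in world coordinates and the head-to-world rotation, plus
#' yaw/pitch/roll under the package's Euler convention.
#'
#' @param marker_tracks frames x k x 3 array of observed marker positions
#'   (labels matching the calibration template rows).
#' @param calibration a [calibrate_head()] result.
#' @param time_s optional frame times.
#' @return `head_pose_series`: data.frame with time, origin (`x`,`y`,`z`),
#'   quaternion (`qw`..`qz`) and `yaw`,`pitch`,`roll` (radians).
#' @export
head_poses <- function(marker_tracks, calibration, time_s = NULL) {
  nf <- dim(marker_tracks)[1]
  time_s <- time_s %||% (seq_len(nf) - 1L)
  out <- data.frame(time_s = time_s, x = NA_real_, y = NA_real_,
                    z = NA_real_, qw = NA_real_, qx = NA_real_,
                    qy = NA_real_, qz = NA_real_, yaw = NA_real_,
                    pitch = NA_real_, roll = NA_real_)
  for (f in seq_len(nf)) {
    obs <- marker_tracks[f, , ]
    if (any(!is.finite(obs))) next
    fit <- fit_rigid_transform(calibration$marker_template, obs)
    R <- fit$transform$rotation
    t <- fit$transform$translation
    q <- rotmat_to_quat(R)
    e <- ypr_from_rotmat(R)
    out[f, 2:11] <- c(t, q, e)
  }
  class(out) <- c("head_pose_series", "data.frame")
  out
}

#' Horizon correction of head poses
#'
#' Defines the horizon as the bird's median head attitude over the
#' recording: subtracts the per-recording median roll and median pitch from
#' every frame (yaw is untouched) and rebuilds the rotations.
#'
#' @param poses a `head_pose_series` from [head_poses()].
#' @return corrected `head_pose_series`; attributes `median_roll`,
#'   `median_pitch` (radians).
#' @export
horizon_correction <- function(poses) {
  if (nrow(poses) < 1L) stop("need at least one pose", call. = FALSE)
  med_roll <- stats::median(poses$roll, na.rm = TRUE)
  med_pitch <- stats::median(poses$pitch, na.rm = TRUE)
  out <- poses
  for (f in seq_len(nrow(poses))) {
    if (!is.finite(poses$yaw[f])) next
    R <- rotmat_from_ypr(poses$yaw[f], poses$pitch[f] - med_pitch,
                         poses$roll[f] - med_roll)
    out[f, c("qw", "qx", "qy", "qz")] <- rotmat_to_quat(R)
    out$pitch[f] <- poses$pitch[f] - med_pitch
    out$roll[f] <- poses$roll[f] - med_roll
  }
  attr(out, "median_roll") <- med_roll
  attr(out, "median_pitch") <- med_pitch
  out
}

#' Repair swapped marker labels on a rigid body
#'
#' Motion-capture software sometimes permutes marker labels within a rigid
#' body. Sections are cut wherever any pairwise inter-marker distance jumps
#' by more than `jump_mm` between adjacent frames (or markers go missing);
#' within each section the label permutation minimizing the total marker
#' displacement across the section boundary is applied. Boundaries that no
#' permutation can reconcile (a genuinely deforming body) are flagged.
#'
#' @param tracks frames x k x 3 array (k <= 6 markers).
#' @param jump_mm jump threshold in millimeters (default 5).
#' @return repaired array; attributes `boundaries` (frame indices),
#'   `permutations` (list), `unrepairable` (frame indices still jumping).
#' @export
repair_marker_labels <- function(tracks, jump_mm = 5) {
  nf <- dim(tracks)[1]; k <- dim(tracks)[2]
  if (k > 6L) stop("marker-label repair supports at most 6 markers",
                   call. = FALSE)
  thr <- jump_mm / 1000
  pair_idx <- utils::combn(k, 2)
  pd <- function(f, tr) {
    p <- tr[f, , ]
    sqrt(rowSums((p[pair_idx[1, ], , drop = FALSE] -
                    p[pair_idx[2, ], , drop = FALSE])^2))
  }
  frame_ok <- vapply(seq_len(nf), function(f) all(is.finite(tracks[f, , ])),
                     logical(1))
  jumps <- rep(FALSE, nf)
  for (f in 2:nf) {
    if (frame_ok[f] && frame_ok[f - 1]) {
      jumps[f] <- any(abs(pd(f, tracks) - pd(f - 1, tracks)) > thr)
    } else {
      jumps[f] <- TRUE                      # missing markers cut a section
    }
  }
  bounds <- which(jumps)
  sec_start <- c(1L, bounds)
  sec_end <- c(bounds - 1L, nf)
  perms <- perm_list(k)
  out <- tracks
  applied <- vector("list", length(sec_start))
  applied[[1]] <- seq_len(k)
  for (s in seq_along(sec_start)[-1]) {
    a <- sec_start[s]; b <- sec_end[s]
    if (b < a) { applied[[s]] <- seq_len(k); next }
    # reference: last finite frame before the section (already repaired)
    ref <- NULL
    for (f in seq(a - 1L, 1L)) {
      if (all(is.finite(out[f, , ]))) { ref <- out[f, , ]; break }
    }
    first <- NULL
    for (f in seq(a, b)) {
      if (all(is.finite(out[f, , ]))) { first <- f; break }
    }
    if (is.null(ref) || is.null(first)) { applied[[s]] <- seq_len(k); next }
    cur <- out[first, , ]
    cost <- vapply(perms, function(p) {
      sum(sqrt(rowSums((cur[p, , drop = FALSE] - ref)^2)))
    }, numeric(1))
    best <- perms[[which.min(cost)]]
    out[a:b, , ] <- out[a:b, best, , drop = FALSE]
    applied[[s]] <- best
  }
  # residual jumps after repair = physically unrepairable boundaries
  unrep <- integer(0)
  for (f in bounds) {
    if (frame_ok[f] && frame_ok[f - 1]) {
      if (any(abs(pd(f, out) - pd(f - 1, out)) > thr)) {
        unrep <- c(unrep, f)
      }
    }
  }
  attr(out, "boundaries") <- bounds
  attr(out, "permutations") <- applied
  attr(out, "unrepairable") <- unrep
  out
}

perm_list <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- perm_list(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

#' Project retinal specializations as world-frame gaze rays
#'
#' Foveas project laterally at azimuth +/- `fovea_azimuth_deg` (from the
#' beak axis, clockwise positive toward the right eye) and elevation 0 (the
#' horizon); the visually sensitive red area is a frontal-lower sector
#' sampled on an azimuth/elevation grid.
#'
#' @param pose one row of a `head_pose_series` (or a list with `x`,`y`,`z`
#'   and `qw`..`qz`).
#' @param fovea_azimuth_deg fovea azimuth magnitude (degrees).
#' @param red_area_az_deg,red_area_el_deg length-2 degree ranges of the red
#'   area sector.
#' @param red_area_step_deg grid step (degrees).
#' @param include_red_area sample the red area as well as the foveas.
#' @return data.frame of rays: `specialization`, origin `x`,`y`,`z`, unit
#'   direction `dx`,`dy`,`dz` (world frame).
#' @export
project_gaze <- function(pose, fovea_azimuth_deg = 75,
                         red_area_az_deg = c(-30, 30),
                         red_area_el_deg = c(-90, -10),
                         red_area_step_deg = 10,
                         include_red_area = TRUE) {
  R <- quat_to_rotmat(c(pose$qw, pose$qx, pose$qy, pose$qz))
  origin <- c(pose$x, pose$y, pose$z)
  az <- deg2rad(c(fovea_azimuth_deg, -fovea_azimuth_deg))
  el <- c(0, 0)
  spec <- c("right_fovea", "left_fovea")
  if (include_red_area) {
    g <- expand.grid(
      az = deg2rad(seq(red_area_az_deg[1], red_area_az_deg[2],
                       by = red_area_step_deg)),
      el = deg2rad(seq(red_area_el_deg[1], red_area_el_deg[2],
                       by = red_area_step_deg)))
    az <- c(az, g$az); el <- c(el, g$el)
    spec <- c(spec, rep("red_area", nrow(g)))
  }
  d_head <- azel_to_dir(az, el)
  d_world <- d_head %*% t(R)
  data.frame(specialization = spec,
             x = origin[1], y = origin[2], z = origin[3],
             dx = d_world[, 1], dy = d_world[, 2], dz = d_world[, 3],
             stringsAsFactors = FALSE)
}

#' Gaze density on a hypothetical sky dome
#'
#' Intersects each gaze ray with the sphere of diameter `dome_diameter_m`
#' centered on the group centroid (forward intersection), converts the
#' intersection to azimuth (0-360 degrees, clockwise from +y) and elevation,
#' and bins it. Rays whose intersection falls below the elevation band and
#' ray origins outside the dome are excluded but counted, so that
#' `sum(bins) + excluded = total rays`.
#'
#' @param rays data.frame from [project_gaze()] (columns `x`..`dz`).
#' @param centroid 3-vector: dome origin (group centroid).
#' @param dome_diameter_m dome diameter (m), default 20.
#' @param az_breaks_deg azimuth bin edges over 0-360 (degrees).
#' @param el_breaks_deg elevation bin edges over the 15-90 band (degrees).
#' @return matrix of counts (azimuth bins x elevation bins) with bin-edge
#'   attributes plus `excluded_below` and `excluded_outside` counts.
#' @export
dome_density <- function(rays, centroid, dome_diameter_m = 20,
                         az_breaks_deg = seq(0, 360, by = 10),
                         el_breaks_deg = seq(15, 90, by = 5)) {
  centroid <- vec3(centroid)
  r <- dome_diameter_m / 2
  H <- matrix(0L, length(az_breaks_deg) - 1L, length(el_breaks_deg) - 1L,
              dimnames = list(NULL, NULL))
  excluded_below <- 0L; excluded_outside <- 0L
  for (i in seq_len(nrow(rays))) {
    o <- c(rays$x[i], rays$y[i], rays$z[i]) - centroid
    d <- unit_vec(c(rays$dx[i], rays$dy[i], rays$dz[i]))
    if (sum(o^2) > r^2) { excluded_outside <- excluded_outside + 1L; next }
    # |o + t d| = r, origin inside -> unique forward root
    b <- sum(o * d)
    disc <- b^2 - (sum(o^2) - r^2)
    t_hit <- -b + sqrt(disc)
    p <- o + t_hit * d
    el <- rad2deg(asin(pmin(pmax(p[3] / r, -1), 1)))
    az <- rad2deg(atan2(p[1], p[2])) %% 360
    if (el < el_breaks_deg[1] || el > el_breaks_deg[length(el_breaks_deg)]) {
      excluded_below <- excluded_below + 1L
      next
    }
    ia <- findInterval(az, az_breaks_deg, rightmost.closed = TRUE,
                       all.inside = TRUE)
    ie <- findInterval(el, el_breaks_deg, rightmost.closed = TRUE,
                       all.inside = TRUE)
    H[ia, ie] <- H[ia, ie] + 1L
  }
  attr(H, "az_breaks_deg") <- az_breaks_deg
  attr(H, "el_breaks_deg") <- el_breaks_deg
  attr(H, "excluded_below") <- excluded_below
  attr(H, "excluded_outside") <- excluded_outside
  H
}
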