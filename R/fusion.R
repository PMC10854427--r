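# Sensor fusion: rigid 6-DOF registration of the acoustic frame into the
# motion-capture global frame, and timestamp alignment between modalities.

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation 3-vector (m).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- vec3(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      det(rotation) < 0) {
    stop("rotation must be orthonormal with det +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1))
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation (%.3f, %.3f, %.3f) m\n",
              rad2deg(ang), x$translation[1], x$translation[2],
              x$translation[3]))
  invisible(x)
}

#' Fit a 6-DOF rigid transform between paired point sets
#'
#' Weighted least-squares rotation and translation (no scale: both frames
#' are metric) mapping `a` onto `b`, via SVD of the centered cross-covariance
#' with determinant correction (the Kabsch solution). The field protocol
#' asks for at least four correspondences measured in both frames; three
#' non-collinear pairs are mathematically sufficient and are accepted with a
#' warning.
#'
#' @param a,b n x 3 matrices of paired points (`a` in the source frame,
#'   e.g. acoustic; `b` in the target frame, e.g. mo-cap global).
#' @param weights optional per-pair non-negative weights.
#' @return list with `transform` (a [rigid_transform()]) and `rms_m`
#'   (root-mean-square residual in meters).
#' @export
fit_rigid_transform <- function(a, b, weights = NULL) {
  a <- as_points3(a); b <- as_points3(b)
  n <- nrow(a)
  if (nrow(b) != n) stop("point sets differ in size", call. = FALSE)
  if (n < 3L) stop("need at least 3 correspondences", call. = FALSE)
  if (n == 3L) warning("only 3 correspondences; the recommended protocol is >= 4")
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  w <- w / sum(w)
  ca <- colSums(a * w); cb <- colSums(b * w)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  # degeneracy: correspondences must span a plane
  sv <- svd(ac * sqrt(w))$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12) || sv[1] < 1e-12) {
    stop("degenerate correspondences (collinear or coincident points)",
         call. = FALSE)
  }
  H <- crossprod(ac * w, bc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - as.numeric(R %*% ca)
  resid <- bc - ac %*% t(R)
  rms <- sqrt(sum(w * rowSums(resid^2)))
  list(transform = rigid_transform(R, t), rms_m = rms)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix or a single 3-vector.
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  single <- is.null(dim(points))
  p <- as_points3(points)
  out <- p %*% t(transform$rotation) +
    rep(transform$translation, each = nrow(p))
  if (single) as.numeric(out) else out
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Compose two rigid transforms
#' @param t2,t1 [rigid_transform()]s; the result applies `t1` first.
#' @return the composed [rigid_transform()] `t2 o t1`.
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Align event timestamps between two recording modalities
#'
#' Finds the constant clock offset `offset` such that `t_a + offset ~ t_b`
#' for matched events: the offset candidate maximizing the number of
#' nearest-neighbor matches within `match_tol_s` is refined as the median of
#' the matched time differences (robust to spurious events in either
#' stream).
#'
#' @param events_a,events_b numeric vectors of event times (s).
#' @param max_lag_s maximum clock offset searched (s).
#' @param match_tol_s tolerance for calling two events a match (s).
#' @return offset in seconds (add to stream a to land on stream b);
#'   attribute `n_matched`.
#' @export
align_timestamps <- function(events_a, events_b, max_lag_s,
                             match_tol_s = 0.05) {
  if (length(events_a) == 0L || length(events_b) == 0L) {
    stop("both event streams must be non-empty", call. = FALSE)
  }
  d <- as.numeric(outer(events_b, events_a, "-"))
  d <- d[abs(d) <= max_lag_s]
  if (length(d) == 0L) {
    stop("no candidate matches within max_lag_s", call. = FALSE)
  }
  # vote for the offset with the most co-occurring differences
  d <- sort(d)
  hi <- findInterval(d + match_tol_s, d)
  lo <- findInterval(d - match_tol_s - 1e-12, d)
  offset0 <- d[which.max(hi - lo)]
  matched <- d[abs(d - offset0) <= match_tol_s]
  offset <- stats::median(matched)
  attr(offset, "n_matched") <- length(matched)
  offset
}

#' Read a correspondence table
#'
#' CSV with columns `xa,ya,za,xb,yb,zb` and optional `weight`.
#' @param path CSV file path.
#' @return list with matrices `a`, `b` and `weights` (or NULL).
#' @export
read_correspondences <- function(path) {
  df <- utils::read.csv(path)
  need <- c("xa", "ya", "za", "xb", "yb", "zb")
  if (!all(need %in% names(df))) {
    stop("correspondence CSV needs columns xa,ya,za,xb,yb,zb", call. = FALSE)
  }
  list(a = as.matrix(df[, c("xa", "ya", "za")]),
       b = as.matrix(df[, c("xb", "yb", "zb")]),
       weights = if ("weight" %in% names(df)) df$weight else NULL)
}

#' Write / read a rigid transform as JSON
#'
#' Stores the rotation row-major plus the translation vector.
#' @param transform a [rigid_transform()].
#' @param path JSON file path.
#' @return `path` (write) or the [rigid_transform()] (read).
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(rotation_row_major = as.numeric(t(transform$rotation)),
         translation = transform$translation),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(x$rotation_row_major, 3, 3, byrow = TRUE),
                  x$translation)
}
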