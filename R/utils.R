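# Internal geometry / numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vec3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x))) {
    stop("expected a finite 3-vector", call. = FALSE)
  }
  x
}

as_points3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("expected an n x 3 matrix of 3D points", call. = FALSE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

rot_x <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3L, 3L)
}
rot_y <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3L, 3L)
}
rot_z <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3L, 3L)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Unit quaternion (w, x, y, z) -> rotation matrix.
quat_to_rotmat <- function(q) {
  q <- as.numeric(q) / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),  2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),  2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x),  1 - 2 * (x^2 + y^2)), 3L, 3L)
}

rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

# Quaternion-uniform random rotation matrix.
random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_rotmat(q / sqrt(sum(q^2)))
}

# Ray-casting point-in-polygon; poly is k x 2 (closed implicitly).
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# O(n) centered moving average with shrinking one-sided windows at the edges.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(x)
  if (width == 1L || n == 0L) return(x)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# O(n) moving sum over trailing window of `width` samples (for envelopes).
moving_sum_centered <- function(x, width) {
  width <- max(1L, as.integer(width))
  n <- length(x)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + (width - 1L - h), n)
  cs[hi + 1L] - cs[lo]
}

pairwise_dist <- function(a, b) {
  # a: n x 3, b: m x 3 -> n x m Euclidean distances
  a <- as_points3(a); b <- as_points3(b)
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Tiny polynomial rolling hash for provenance sidecars (no digest dependency).
content_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
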