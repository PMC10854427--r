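# Trajectory analytics: speed, behavior classification, synchronized
# foraging initiations, Jaccard behavioral similarity, and leadership
# networks from directional correlation with delay.

#' Trajectory of one individual
#'
#' @param id individual identifier.
#' @param time_s strictly increasing, uniformly spaced frame times (s).
#' @param positions n x 3 matrix of 3D positions (m).
#' @param quaternions optional n x 4 matrix of unit orientation quaternions
#'   (w, x, y, z).
#' @param frame_rate_hz frame rate; inferred from `time_s` when missing.
#' @param behavior optional per-frame ground-truth regime labels (simulator).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(id, time_s, positions, quaternions = NULL,
                       frame_rate_hz = NULL, behavior = NULL) {
  positions <- as_points3(positions)
  n <- length(time_s)
  if (nrow(positions) != n) stop("time_s and positions disagree", call. = FALSE)
  if (n >= 2L) {
    dt <- diff(time_s)
    if (any(dt <= 0)) stop("frame times must be strictly increasing",
                           call. = FALSE)
    if (is.null(frame_rate_hz)) frame_rate_hz <- 1 / stats::median(dt)
  }
  structure(list(id = id, time_s = as.numeric(time_s), positions = positions,
                 quaternions = quaternions, frame_rate_hz = frame_rate_hz,
                 behavior = behavior), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> id %s: %d frames @ %g Hz (%.1f s)\n",
              as.character(x$id), length(x$time_s), x$frame_rate_hz,
              diff(range(x$time_s))))
  invisible(x)
}

check_uniform_times <- function(time_s, tol = 1e-6) {
  dt <- diff(time_s)
  if (length(dt) && (max(dt) - min(dt)) > tol * stats::median(dt)) {
    stop("irregular timestamps: resample the trajectory first", call. = FALSE)
  }
  invisible(TRUE)
}

traj_velocity <- function(traj) {
  # central differences, one-sided at the ends; n x 3 (m/s)
  p <- traj$positions
  t <- traj$time_s
  n <- nrow(p)
  v <- matrix(0, n, 3)
  if (n >= 3L) {
    idx <- 2:(n - 1)
    v[idx, ] <- (p[idx + 1L, ] - p[idx - 1L, ]) / (t[idx + 1L] - t[idx - 1L])
  }
  if (n >= 2L) {
    v[1, ] <- (p[2, ] - p[1, ]) / (t[2] - t[1])
    v[n, ] <- (p[n, ] - p[n - 1L, ]) / (t[n] - t[n - 1L])
  }
  v
}

#' Per-frame speed of a trajectory
#'
#' Central-difference velocity (one-sided at the endpoints), component-wise
#' moving-average smoothed over `smooth_window_s`, then the Euclidean norm.
#'
#' @param traj a [trajectory()].
#' @param smooth_window_s smoothing window (s); 0 disables smoothing.
#' @return numeric vector of speeds (m/s), one per frame.
#' @export
compute_speed <- function(traj, smooth_window_s = 0.2) {
  if (length(traj$time_s) < 3L) stop("need at least 3 frames", call. = FALSE)
  check_uniform_times(traj$time_s)
  v <- traj_velocity(traj)
  if (smooth_window_s > 0) {
    w <- round(smooth_window_s * traj$frame_rate_hz)
    if (w > 1L) v <- apply(v, 2, moving_average, width = w)
  }
  sqrt(rowSums(v^2))
}

#' Classify per-frame behavior from height and speed
#'
#' The class rules (half-open height bands; the speed tie `v = v_split`
#' counts as flying):
#' * foraging: `z < z_low`
#' * flying:   `z >= z_low` and `v >= v_split`
#' * perching: `z_low <= z < z_high` and `v < v_split`
#' * other:    `z >= z_high` and `v < v_split`
#'
#' @param traj a [trajectory()].
#' @param z_low,z_high height thresholds (m), defaults 0.5 and 3.
#' @param v_split speed threshold (m/s), default 1.
#' @param smooth_window_s speed smoothing window (s).
#' @return a `behavior_series`: data.frame with `time_s`, `label`, `z`,
#'   `speed`; thresholds stored as attributes.
#' @export
classify_behavior <- function(traj, z_low = 0.5, z_high = 3, v_split = 1,
                              smooth_window_s = 0.2) {
  v <- compute_speed(traj, smooth_window_s)
  z <- traj$positions[, 3]
  label <- ifelse(z < z_low, "foraging",
           ifelse(v >= v_split, "flying",
           ifelse(z < z_high, "perching", "other")))
  out <- data.frame(time_s = traj$time_s, label = label, z = z, speed = v,
                    stringsAsFactors = FALSE)
  attr(out, "id") <- traj$id
  attr(out, "thresholds") <- c(z_low = z_low, z_high = z_high,
                               v_split = v_split)
  class(out) <- c("behavior_series", "data.frame")
  out
}

behavior_categories <- c("perching", "foraging", "flying", "other")

#' Synchronized foraging initiations
#'
#' An arrival is a transition into the foraging class. Arrivals (pooled over
#' individuals, time-ordered) are chained while consecutive gaps are below
#' `dt_threshold_s`; each maximal chain is one initiation event, and each
#' individual is counted at most once per event.
#'
#' @param series_list list of `behavior_series` (one per individual), as
#'   returned by [classify_behavior()].
#' @param dt_threshold_s chaining threshold between consecutive arrivals (s).
#' @return data.frame with one row per event: `t_start_s`, `t_end_s`,
#'   `size`, `members` (comma-separated ids in arrival order).
#' @export
foraging_initiations <- function(series_list, dt_threshold_s = 10) {
  if (length(series_list) < 1L) stop("need at least one individual",
                                     call. = FALSE)
  arr <- do.call(rbind, lapply(series_list, function(s) {
    lab <- s$label
    new <- which(lab == "foraging" & c(TRUE, lab[-length(lab)] != "foraging"))
    if (length(new) == 0L) return(NULL)
    data.frame(id = as.character(attr(s, "id")), t = s$time_s[new],
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
                      size = integer(0), members = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(arr) || nrow(arr) == 0L) return(empty)
  arr <- arr[order(arr$t), ]
  chain_id <- cumsum(c(1, diff(arr$t) >= dt_threshold_s))
  do.call(rbind, lapply(split(arr, chain_id), function(ch) {
    ids <- unique(ch$id)
    data.frame(t_start_s = ch$t[1], t_end_s = ch$t[nrow(ch)],
               size = length(ids), members = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Jaccard similarity of two behavior series
#'
#' Per category `c`: `J_c = |frames both in c| / |frames either in c|`
#' (categories with an empty union are reported as `NA` and excluded from
#' the mean). The overall index is emitted in two conventions: the
#' ratio-of-sums across categories and the mean of per-category indices.
#'
#' @param series_i,series_j `behavior_series` on an identical time base.
#' @return list with `per_category` (named vector), `overall`
#'   (ratio-of-sums) and `mean_per_category`.
#' @export
jaccard_similarity <- function(series_i, series_j) {
  if (nrow(series_i) != nrow(series_j) ||
      max(abs(series_i$time_s - series_j$time_s)) > 1e-9) {
    stop("behavior series must share the same time base", call. = FALSE)
  }
  both_tot <- 0; either_tot <- 0
  per <- vapply(behavior_categories, function(cat) {
    a <- series_i$label == cat
    b <- series_j$label == cat
    both <- sum(a & b); either <- sum(a | b)
    both_tot <<- both_tot + both
    either_tot <<- either_tot + either
    if (either == 0L) NA_real_ else both / either
  }, numeric(1))
  list(per_category = per,
       overall = if (either_tot == 0L) NA_real_ else both_tot / either_tot,
       mean_per_category = mean(per, na.rm = TRUE))
}

traj_overlap_index <- function(ti, tj) {
  # indices of tj matching each frame of ti (same frame rate assumed)
  j <- round((ti$time_s - tj$time_s[1]) * tj$frame_rate_hz) + 1L
  ok <- j >= 1L & j <= length(tj$time_s)
  list(i = which(ok), j = j[ok])
}

#' Directional correlation with delay
#'
#' For unit flight-velocity vectors of two individuals,
#' `C(tau) = < v_i(t) . v_j(t + tau) >`, averaged over all frames where both
#' individuals are in flight (speed at least `min_speed_m_s`). The delay tau
#' is sampled at frame resolution over `tau_range_s`. A positive `tau` at
#' the maximum means individual `j` follows (copies the flight direction of)
#' individual `i` after that delay.
#'
#' @param traj_i,traj_j [trajectory()]s on the same frame rate.
#' @param tau_range_s length-2 delay range (s).
#' @param min_speed_m_s flight-speed threshold (m/s).
#' @param smooth_window_s speed smoothing window used for the flight mask.
#' @return data.frame with `tau_s`, `C`, `n` (frame pairs averaged); zero
#'   rows when the tracks share no flight frames.
#' @export
directional_correlation <- function(traj_i, traj_j, tau_range_s = c(-2, 2),
                                    min_speed_m_s = 1,
                                    smooth_window_s = 0.2) {
  rate <- traj_i$frame_rate_hz
  vi <- traj_velocity(traj_i); vj <- traj_velocity(traj_j)
  si <- compute_speed(traj_i, smooth_window_s)
  sj <- compute_speed(traj_j, smooth_window_s)
  ni <- sqrt(rowSums(vi^2)); nj <- sqrt(rowSums(vj^2))
  ui <- vi / pmax(ni, 1e-12); uj <- vj / pmax(nj, 1e-12)
  oki <- si >= min_speed_m_s & ni > 1e-9
  okj <- sj >= min_speed_m_s & nj > 1e-9
  lag0 <- round((traj_j$time_s[1] - traj_i$time_s[1]) * rate)
  lags <- seq(round(tau_range_s[1] * rate), round(tau_range_s[2] * rate))
  n_i <- nrow(ui); n_j <- nrow(uj)
  out <- lapply(lags, function(k) {
    # frame t of i pairs with frame (t + k) of i's clock = index t + k - lag0 of j
    jidx <- seq_len(n_i) + k - lag0
    ok <- jidx >= 1L & jidx <= n_j
    ii <- which(ok); jj <- jidx[ok]
    use <- oki[ii] & okj[jj]
    if (!any(use)) return(c(NA_real_, 0))
    dots <- rowSums(ui[ii[use], , drop = FALSE] * uj[jj[use], , drop = FALSE])
    c(mean(dots), sum(use))
  })
  out <- do.call(rbind, out)
  res <- data.frame(tau_s = lags / rate, C = out[, 1], n = out[, 2])
  res[res$n > 0, , drop = FALSE]
}

#' Leadership network from highly correlated segments
#'
#' For every pair of individuals the common timeline is cut into
#' consecutive windows of `window_s`; a window is a highly correlated
#' segment (HCS) when `max_tau C(tau) >= C_min` with both birds in flight
#' for at least `min_flight_frac` of the window. The symmetric edge weight
#' is the summed HCS duration in seconds.
#'
#' @param trajs list of [trajectory()]s.
#' @param C_min correlation threshold for an HCS.
#' @param window_s window length (s).
#' @param tau_range_s delay range searched (s).
#' @param min_speed_m_s flight-speed threshold (m/s).
#' @param min_flight_frac minimum fraction of frame pairs in flight for a
#'   window to be evaluable.
#' @return `hcs_network`: list with `nodes`, `edges` (data.frame `id_i`,
#'   `id_j`, `weight_s`) and `params`.
#' @export
hcs_network <- function(trajs, C_min = 0.9, window_s = 2,
                        tau_range_s = c(-2, 2), min_speed_m_s = 1,
                        min_flight_frac = 0.5) {
  if (length(trajs) < 2L) stop("need at least 2 individuals", call. = FALSE)
  ids <- vapply(trajs, function(t) as.character(t$id), character(1))
  pairs <- utils::combn(length(trajs), 2)
  edges <- data.frame(id_i = character(0), id_j = character(0),
                      weight_s = numeric(0), stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pairs))) {
    ti <- trajs[[pairs[1, p]]]; tj <- trajs[[pairs[2, p]]]
    t0 <- max(ti$time_s[1], tj$time_s[1])
    t1 <- min(ti$time_s[length(ti$time_s)], tj$time_s[length(tj$time_s)])
    weight <- 0
    if (t1 - t0 >= window_s) {
      starts <- seq(t0, t1 - window_s, by = window_s)
      for (ws in starts) {
        wi <- window_traj(ti, ws, ws + window_s)
        wj <- window_traj(tj, ws, ws + window_s)
        if (is.null(wi) || is.null(wj)) next
        dc <- directional_correlation(wi, wj, tau_range_s, min_speed_m_s)
        need <- min_flight_frac * window_s * ti$frame_rate_hz
        dc <- dc[dc$n >= need, , drop = FALSE]
        if (nrow(dc) && max(dc$C, na.rm = TRUE) >= C_min) {
          weight <- weight + window_s
        }
      }
    }
    if (weight > 0) {
      edges <- rbind(edges, data.frame(id_i = ids[pairs[1, p]],
                                       id_j = ids[pairs[2, p]],
                                       weight_s = weight,
                                       stringsAsFactors = FALSE))
    }
  }
  structure(list(nodes = ids, edges = edges,
                 params = list(C_min = C_min, window_s = window_s,
                               tau_range_s = tau_range_s,
                               min_speed_m_s = min_speed_m_s)),
            class = "hcs_network")
}

window_traj <- function(traj, t0, t1) {
  # sub-trajectory on [t0, t1); context for windowed correlation
  sel <- traj$time_s >= t0 - 1e-9 & traj$time_s < t1 - 1e-9
  if (sum(sel) < 3L) return(NULL)
  trajectory(traj$id, traj$time_s[sel], traj$positions[sel, , drop = FALSE],
             frame_rate_hz = traj$frame_rate_hz)
}

#' @export
print.hcs_network <- function(x, ...) {
  cat(sprintf("<hcs_network> %d nodes, %d edges (C_min = %g, window = %g s)\n",
              length(x$nodes), nrow(x$edges), x$params$C_min,
              x$params$window_s))
  invisible(x)
}

#' Convert an HCS network to igraph / write it out
#'
#' @param network an [hcs_network()].
#' @return an igraph graph with `weight` edge attribute (in seconds).
#' @export
as_igraph.hcs_network <- function(network) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$nodes),
                            name = as.character(network$nodes))
  if (nrow(network$edges)) {
    g <- igraph::add_edges(
      g, rbind(network$edges$id_i, network$edges$id_j),
      weight = network$edges$weight_s)
  }
  g
}

#' @rdname as_igraph.hcs_network
#' @param path output file; `write_hcs_network` writes the edge list as CSV
#'   and, if `graphml` is given, GraphML via igraph.
#' @param graphml optional GraphML output path.
#' @export
write_hcs_network <- function(network, path, graphml = NULL) {
  utils::write.csv(network$edges, path, row.names = FALSE)
  if (!is.null(graphml)) {
    igraph::write_graph(as_igraph.hcs_network(network), graphml,
                        format = "graphml")
  }
  invisible(path)
}
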