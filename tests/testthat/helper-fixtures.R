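# Shared fixtures and independent oracles, built in code at test time.

# small arena with a light audio rate for fast renders
small_arena <- function(seed = 1L, fs = 20000) {
  arena_config(audio_fs_hz = fs, seed = seed)
}

# geometric TOADs of a source at `src` for a mic_array (the forward model
# used as the independent oracle for localization)
geometric_toads <- function(src, mics, ref = NULL) {
  d <- sqrt(rowSums((mics$positions -
                       rep(src, each = nrow(mics$positions)))^2))
  if (is.null(ref)) ref <- which.min(d)
  tau <- (d - d[ref]) / mics$speed_of_sound_m_s
  attr(tau, "ref") <- ref
  tau
}

# brute-force directional correlation sweep (independent of the package's
# vectorized implementation): plain loops over lags and frames
oracle_dir_corr <- function(vi, vj, lags) {
  ui <- vi / sqrt(rowSums(vi^2))
  uj <- vj / sqrt(rowSums(vj^2))
  vapply(lags, function(k) {
    s <- 0; n <- 0
    for (t in seq_len(nrow(ui))) {
      t2 <- t + k
      if (t2 >= 1 && t2 <= nrow(uj)) {
        s <- s + sum(ui[t, ] * uj[t2, ])
        n <- n + 1
      }
    }
    s / n
  }, numeric(1))
}

# straight-line constant-velocity trajectory
line_traj <- function(id, v, n = 400, rate = 100, origin = c(1, 1, 1)) {
  t <- (seq_len(n) - 1) / rate
  trajectory(id, t, cbind(origin[1] + v[1] * t, origin[2] + v[2] * t,
                          origin[3] + v[3] * t), frame_rate_hz = rate)
}

# behavior series with prescribed labels on a shared clock
label_series <- function(labels, id = "x", rate = 100) {
  s <- data.frame(time_s = (seq_along(labels) - 1) / rate, label = labels,
                  z = 0, speed = 0, stringsAsFactors = FALSE)
  attr(s, "id") <- id
  class(s) <- c("behavior_series", "data.frame")
  s
}

# marker pattern whose every label transposition moves some pairwise
# distance by > 20 mm (uniquely identifiable, like a real backpack pattern)
swap_markers <- function() {
  rbind(c(-0.0234, 0.0246, -0.0172), c(-0.0007, -0.0054, 0.0192),
        c(-0.0074, 0.0056, -0.0139), c(0.0222, -0.0241, 0.0193))
}

# a rigid 4-marker head with keypoints, plus poses moved by (R, t)
head_fixture <- function() {
  list(markers = rbind(c(0.02, 0.01, 0.03), c(-0.02, 0.015, 0.03),
                       c(0, -0.02, 0.035), c(0.01, 0, 0.045)),
       eye_l = c(-0.01, 0, 0), eye_r = c(0.01, 0, 0),
       beak = c(0, 0.02, -0.01))
}

moved_markers <- function(markers, R, t) {
  markers %*% t(R) + rep(t, each = nrow(markers))
}

# scripted Y-maze walk: waypoints (arm, frac) visited at constant speed
maze_walk <- function(maze, waypoints, dt = 0.02, speed = 0.4,
                      dwell_s = 0.8) {
  pt <- function(w) {
    th <- maze$arm_angles_rad[w$arm]
    (maze$center_radius_m + w$frac * maze$arm_length_m) *
      c(cos(th), sin(th))
  }
  pos <- pt(waypoints[[1]])
  t <- 0
  out <- list(c(t, pos))
  append_dwell <- function() {
    for (k in seq_len(round(dwell_s / dt))) {
      t <<- t + dt
      out[[length(out) + 1L]] <<- c(t, pos)
    }
  }
  append_dwell()
  for (w in waypoints[-1]) {
    # walk via the junction
    for (tgt in list(c(0, 0), pt(w))) {
      repeat {
        d <- sqrt(sum((tgt - pos)^2))
        if (d <= speed * dt) { pos <- tgt; break }
        pos <- pos + (tgt - pos) / d * speed * dt
        t <- t + dt
        out[[length(out) + 1L]] <- c(t, pos)
      }
    }
    append_dwell()
  }
  m <- do.call(rbind, out)
  data.frame(time_s = m[, 1], x = m[, 2], y = m[, 3])
}
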