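# Synthetic arena: regime-switching bird trajectories, call waveforms, and
# physically consistent multichannel audio rendering with known ground
# truth. Everything is deterministic in the arena seed.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

default_regime_params <- function() {
  list(
    regimes = c("perch", "forage", "flight"),
    dwell_s = list(perch = 20, forage = 15),
    min_dwell_s = 2,
    flight_speed_m_s = c(2, 6),
    ramp_s = 0.4,
    perch_jitter_sd_m = 0.005,
    perch_jitter_ar = 0.98,
    forage_speed_sd_m_s = 0.15,
    followers = NULL)
}

regime_to_class <- function(regime) {
  c(perch = "perching", forage = "foraging", flight = "flying")[regime]
}

random_point_in_polygon <- function(poly) {
  bb <- apply(poly, 2, range)
  repeat {
    p <- c(stats::runif(1, bb[1, 1], bb[2, 1]),
           stats::runif(1, bb[1, 2], bb[2, 2]))
    if (point_in_polygon(p[1], p[2], poly)) return(p)
  }
}

# Quadratic-Bezier flight with a C2 (smoothstep-velocity) speed profile.
flight_segment <- function(from, to, v_cruise, rate, height_m, ramp_s) {
  L0 <- sqrt(sum((to - from)^2))
  mid <- (from + to) / 2
  lat <- cross3(unit_vec(to - from + c(0, 0, 1e-9)), c(0, 0, 1))
  mid <- mid + lat * stats::runif(1, -1.2, 1.2)
  mid[3] <- min(max(from[3], to[3]) + stats::runif(1, 0.4, 1.2),
                height_m - 0.3)
  u <- seq(0, 1, length.out = 600)
  P <- outer((1 - u)^2, from) + outer(2 * u * (1 - u), mid) + outer(u^2, to)
  seglen <- sqrt(rowSums(diff(P)^2))
  cumlen <- c(0, cumsum(seglen))
  L <- cumlen[length(cumlen)]
  v_c <- min(v_cruise, L / (1.1 * ramp_s))    # short hops: slower cruise
  v_c <- max(v_c, 1.2)
  T <- ramp_s + L / v_c
  tt <- seq(0, T, by = 1 / rate)
  smoothstep_int <- function(tau) 2.5 * tau^4 - 3 * tau^5 + tau^6
  s_of_t <- function(t) {
    t <- pmin(pmax(t, 0), T)
    s <- numeric(length(t))
    a <- t < ramp_s
    s[a] <- v_c * ramp_s * smoothstep_int(t[a] / ramp_s)
    b <- t >= ramp_s & t <= T - ramp_s
    s[b] <- v_c * ramp_s / 2 + v_c * (t[b] - ramp_s)
    cc <- t > T - ramp_s
    s[cc] <- L - v_c * ramp_s * smoothstep_int((T - t[cc]) / ramp_s)
    s
  }
  s <- pmin(s_of_t(tt), L)
  uu <- stats::approx(cumlen, seq(0, 1, length.out = length(cumlen)),
                      xout = s, rule = 2)$y
  pos <- outer((1 - uu)^2, from) + outer(2 * uu * (1 - uu), mid) +
    outer(uu^2, to)
  pos
}

# Maneuvering flight as a correlated random walk on heading: the yaw rate
# is an AR(1) (Ornstein-Uhlenbeck) process with ~2.5 rad/s RMS (a ~1.6 m
# turning radius at cruise speed), pitch and speed are mean-reverting, and
# walls reflect the heading.
wander_flight <- function(n_frames, config, rp) {
  rate <- config$frame_rate_hz
  dt <- 1 / rate
  v_lo <- rp$flight_speed_m_s[1]; v_hi <- rp$flight_speed_m_s[2]
  v_mean <- (v_lo + v_hi) / 2
  rho_r <- 0.97
  yaw_rate_rms <- rp$yaw_rate_rms %||% 2.5
  r <- ar1_jitter(n_frames, yaw_rate_rms, rho_r)
  pitch <- ar1_jitter(n_frames, 0.2, 0.99)
  speed <- pmin(pmax(v_mean + ar1_jitter(n_frames, (v_hi - v_lo) / 4, 0.99),
                     v_lo), v_hi)
  yaw <- cumsum(r * dt) + stats::runif(1, 0, 2 * pi)
  p <- matrix(NA_real_, n_frames, 3)
  p[1, ] <- c(stats::runif(1, 2, config$length_m - 2),
              stats::runif(1, 1.5, config$width_m - 1.5),
              stats::runif(1, 1.2, min(2.8, config$height_m - 0.6)))
  margin <- 0.5
  z_lo <- 0.7; z_hi <- min(3, config$height_m - 0.4)
  for (k in 2:n_frames) {
    d <- c(cos(yaw[k]) * cos(pitch[k]), sin(yaw[k]) * cos(pitch[k]),
           sin(pitch[k]))
    cand <- p[k - 1, ] + speed[k] * d * dt
    if (cand[1] < margin || cand[1] > config$length_m - margin) {
      yaw[k:n_frames] <- pi - yaw[k:n_frames]
      d[1] <- -d[1]
      cand <- p[k - 1, ] + speed[k] * d * dt
    }
    if (cand[2] < margin || cand[2] > config$width_m - margin) {
      yaw[k:n_frames] <- -yaw[k:n_frames]
      d[2] <- -d[2]
      cand <- p[k - 1, ] + speed[k] * d * dt
    }
    if (cand[3] < z_lo || cand[3] > z_hi) {
      pitch[k:n_frames] <- -pitch[k:n_frames]
      d[3] <- -d[3]
      cand <- p[k - 1, ] + speed[k] * d * dt
    }
    p[k, ] <- cand
  }
  p
}

ar1_jitter <- function(n, sd, rho) {
  e <- stats::rnorm(n, 0, sd)
  as.numeric(stats::filter(e * sqrt(1 - rho^2), rho, method = "recursive"))
}

simulate_one_track <- function(config, rp, n_frames) {
  rate <- config$frame_rate_hz
  zp <- config$zone_plan
  regimes <- rp$regimes
  unknown <- setdiff(regimes, c("perch", "forage", "flight"))
  if (length(unknown)) {
    stop("unknown regime name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pos <- matrix(NA_real_, 0, 3)
  lab <- character(0)
  perch_site <- function() {
    ps <- zp$perch_positions
    ps[sample(nrow(ps), 1L), ] + c(stats::runif(2, -0.15, 0.15), 0)
  }
  forage_site <- function() c(random_point_in_polygon(zp$foraging_polygon), 0.05)
  air_site <- function() c(stats::runif(1, 1, config$length_m - 1),
                           stats::runif(1, 1, config$width_m - 1),
                           stats::runif(1, 1.0, min(3, config$height_m - 0.5)))
  dwell_frames <- function(state) {
    mean_dwell <- rp$dwell_s[[state]] %||% 10
    round((rp$min_dwell_s + stats::rexp(1, 1 / mean_dwell)) * rate)
  }
  stationary_block <- function(center, nf, state) {
    jit <- vapply(1:3, function(k) ar1_jitter(nf, rp$perch_jitter_sd_m,
                                              rp$perch_jitter_ar), numeric(nf))
    if (state == "forage") {
      # slow correlated wander on the floor
      vx <- ar1_jitter(nf, rp$forage_speed_sd_m_s, 0.95) / rate
      vy <- ar1_jitter(nf, rp$forage_speed_sd_m_s, 0.95) / rate
      walk <- cbind(cumsum(vx), cumsum(vy), 0)
      bb <- apply(zp$foraging_polygon, 2, range)
      out <- cbind(center[1] + walk[, 1], center[2] + walk[, 2],
                   center[3] + jit[, 3] * 0.2)
      out[, 1] <- pmin(pmax(out[, 1], bb[1, 1] + 0.1), bb[2, 1] - 0.1)
      out[, 2] <- pmin(pmax(out[, 2], bb[1, 2] + 0.1), bb[2, 2] - 0.1)
      out
    } else {
      cbind(center[1] + jit[, 1], center[2] + jit[, 2], center[3] + jit[, 3])
    }
  }
  # single-regime worlds
  if (identical(sort(unique(regimes)), "perch")) {
    p <- perch_site()
    pos <- stationary_block(p, n_frames, "perch")
    lab <- rep("perch", n_frames)
  } else if (identical(sort(unique(regimes)), "forage")) {
    p <- forage_site()
    pos <- stationary_block(p, n_frames, "forage")
    lab <- rep("forage", n_frames)
  } else if (identical(sort(unique(regimes)), "flight")) {
    # continuous maneuvering flight: correlated-heading wander with
    # reflective walls (tight banked turns, as in a confined arena)
    pos <- wander_flight(n_frames, config, rp)
    lab <- rep("flight", n_frames)
  } else {
    if (!"flight" %in% regimes) {
      stop("regimes combining zones require the 'flight' regime", call. = FALSE)
    }
    state <- sample(intersect(c("perch", "forage"), regimes), 1L)
    cur <- if (state == "perch") perch_site() else forage_site()
    while (nrow(pos) < n_frames) {
      nf <- dwell_frames(state)
      blk <- stationary_block(cur, nf, state)
      pos <- rbind(pos, blk)
      lab <- c(lab, rep(state, nf))
      cur <- blk[nrow(blk), ]
      nxt <- if (state == "perch" && "forage" %in% regimes) "forage"
             else if ("perch" %in% regimes) "perch" else state
      tgt <- if (nxt == "perch") perch_site() else forage_site()
      v <- stats::runif(1, rp$flight_speed_m_s[1], rp$flight_speed_m_s[2])
      seg <- flight_segment(cur, tgt, v, rate, config$height_m, rp$ramp_s)
      pos <- rbind(pos, seg)
      lab <- c(lab, rep("flight", nrow(seg)))
      cur <- tgt
      state <- nxt
    }
  }
  pos <- pos[seq_len(n_frames), , drop = FALSE]
  lab <- lab[seq_len(n_frames)]
  # clip to arena box
  pos[, 1] <- pmin(pmax(pos[, 1], 0), config$length_m)
  pos[, 2] <- pmin(pmax(pos[, 2], 0), config$width_m)
  pos[, 3] <- pmin(pmax(pos[, 3], 0), config$height_m)
  list(pos = pos, lab = lab)
}

#' Simulate regime-switching trajectories with ground truth
#'
#' Each independent individual alternates perch and foraging bouts
#' (exponential dwell times) connected by smooth curved flights whose
#' cruise speed is drawn from `flight_speed_m_s`; perch sites carry
#' zero-mean AR(1) jitter (sd 5 mm). Optional leader-follower pairs make
#' the follower's velocity equal the leader's delayed by `tau_f` plus
#' isotropic noise, emulating two birds flying the same 3D path. The
#' per-frame generating regime is stored as ground truth on each track.
#'
#' @param config an [arena_config()]; its seed determines the output.
#' @param n_individuals number of birds (>= 1).
#' @param duration_s track duration (s).
#' @param regime_params optional list overriding the defaults: `regimes`
#'   (subset of perch/forage/flight), `dwell_s`, `flight_speed_m_s`,
#'   `followers` (list of `list(leader=, follower=, tau_f=, noise=)`), etc.
#' @return list of [trajectory()] objects with `$behavior` ground truth.
#' @export
simulate_trajectories <- function(config, n_individuals, duration_s,
                                  regime_params = list()) {
  if (n_individuals < 1L) stop("n_individuals must be >= 1", call. = FALSE)
  stopifnot_scalar_num(duration_s, "duration_s", positive = TRUE)
  rp <- utils::modifyList(default_regime_params(), regime_params)
  for (f in rp$followers) {
    if (f$tau_f >= duration_s) {
      stop("follower delay tau_f exceeds the track duration", call. = FALSE)
    }
  }
  rate <- config$frame_rate_hz
  n_frames <- round(duration_s * rate)
  tt <- (seq_len(n_frames) - 1L) / rate
  follower_ids <- vapply(rp$followers %||% list(),
                         function(f) as.integer(f$follower), integer(1))
  with_seed(config$seed, {
    tracks <- vector("list", n_individuals)
    for (i in seq_len(n_individuals)) {
      if (i %in% follower_ids) next
      tr <- simulate_one_track(config, rp, n_frames)
      tracks[[i]] <- trajectory(sprintf("bird%02d", i), tt, tr$pos,
                                frame_rate_hz = rate, behavior = tr$lab)
    }
    for (f in rp$followers %||% list()) {
      lead <- tracks[[f$leader]]
      if (is.null(lead)) stop("follower's leader was not simulated",
                              call. = FALSE)
      lag <- round(f$tau_f * rate)
      vl <- traj_velocity(lead)
      noise <- f$noise %||% 0
      vf <- matrix(0, n_frames, 3)
      if (lag < n_frames) {
        vf[(lag + 1L):n_frames, ] <- vl[seq_len(n_frames - lag), , drop = FALSE]
      }
      if (noise > 0) vf <- vf + matrix(stats::rnorm(3 * n_frames, 0, noise),
                                       n_frames, 3)
      x0 <- lead$positions[1, ] + c(0.3, 0.4, 0)
      pos <- rbind(x0, sweep(apply(vf[-1, , drop = FALSE] / rate, 2, cumsum),
                             2, x0, "+"))
      pos[, 1] <- pmin(pmax(pos[, 1], 0), config$length_m)
      pos[, 2] <- pmin(pmax(pos[, 2], 0), config$width_m)
      pos[, 3] <- pmin(pmax(pos[, 3], 0), config$height_m)
      lab <- c(rep(lead$behavior[1], min(lag, n_frames)),
               lead$behavior[seq_len(max(n_frames - lag, 0))])
      tracks[[f$follower]] <- trajectory(sprintf("bird%02d", f$follower), tt,
                                         pos, frame_rate_hz = rate,
                                         behavior = lab)
    }
    names(tracks) <- vapply(tracks, function(t) as.character(t$id),
                            character(1))
    tracks
  })
}

#' Synthesize a harmonic call waveform
#'
#' A harmonic stack (amplitudes 1/h) with an optional linear sweep of the
#' fundamental, cosine-tapered onset and offset, normalized to peak
#' amplitude 1. Used as the ground-truth call fixture for rendering and
#' spectral-feature tests.
#'
#' @param f0_hz fundamental frequency at onset (Hz), `0 < f0 < fs/2`.
#' @param n_harmonics number of harmonics (1 = pure tone).
#' @param duration_s duration (s).
#' @param chirp_rate_hz_s linear sweep rate of the fundamental (Hz/s).
#' @param fs_hz sample rate (Hz).
#' @param taper_frac fraction of the duration tapered at each edge.
#' @return numeric waveform vector.
#' @export
synth_call_waveform <- function(f0_hz, n_harmonics = 1L, duration_s,
                                chirp_rate_hz_s = 0, fs_hz,
                                taper_frac = 0.1) {
  stopifnot_scalar_num(duration_s, "duration_s", positive = TRUE)
  if (f0_hz <= 0 || f0_hz >= fs_hz / 2) {
    stop("need 0 < f0 < fs/2", call. = FALSE)
  }
  f_max <- max(f0_hz, f0_hz + chirp_rate_hz_s * duration_s)
  for (h in seq_len(n_harmonics)) {
    if (f_max * h >= fs_hz / 2) {
      stop(sprintf("harmonic %d (%.0f Hz) aliases at fs = %g Hz",
                   h, f_max * h, fs_hz), call. = FALSE)
    }
  }
  n <- max(round(duration_s * fs_hz), 2L)
  t <- (seq_len(n) - 1L) / fs_hz
  phase <- f0_hz * t + 0.5 * chirp_rate_hz_s * t^2
  x <- rowSums(vapply(seq_len(n_harmonics),
                      function(h) sin(2 * pi * h * phase) / h, numeric(n)))
  nt <- max(round(taper_frac * n), 1L)
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nt)))
  x[seq_len(nt)] <- x[seq_len(nt)] * ramp
  x[(n - nt + 1L):n] <- x[(n - nt + 1L):n] * rev(ramp)
  x / max(abs(x))
}

# Windowed-sinc fractional-delay kernel (Hann window, half-width hw).
frac_delay_kernel <- function(frac, hw = 32L) {
  k <- (-hw):hw
  x <- k - frac
  s <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
  w <- 0.5 * (1 + cos(pi * (x) / (hw + 1)))
  w[abs(x) > hw + 1] <- 0
  s * w
}

#' Render multichannel arena audio for a scene
#'
#' Each ground-truth sound event is delayed per channel by `distance / c`
#' (sub-sample accurate via windowed-sinc interpolation), attenuated by
#' spherical spreading `1/r`, and summed into the channel buffers. White
#' Gaussian noise is added so that the requested event SNR holds at the
#' nearest microphone (median over events); with `noise_rms` given, that
#' floor is used verbatim instead.
#'
#' @param scene a [simulate_scene()] scene (events + waveforms).
#' @param mics a [mic_array()].
#' @param snr_db target per-event SNR at the nearest microphone (dB).
#' @param noise_rms optional explicit noise RMS overriding `snr_db`.
#' @param duration_s length of the rendered block (defaults to the scene
#'   trajectory duration).
#' @return an [audio_block()] (channels x samples).
#' @export
render_audio <- function(scene, mics, snr_db = 20, noise_rms = NULL,
                         duration_s = NULL) {
  fs <- scene$config$audio_fs_hz
  c_sound <- mics$speed_of_sound_m_s
  if (is.null(duration_s)) {
    duration_s <- if (length(scene$trajectories)) {
      max(vapply(scene$trajectories,
                 function(tr) tr$time_s[length(tr$time_s)], numeric(1)))
    } else if (nrow(scene$events)) max(scene$events$t_emit_s) + 1 else 1
  }
  n <- round(duration_s * fs)
  n_ch <- nrow(mics$positions)
  out <- matrix(0, n_ch, n)
  ev <- scene$events
  p_nearest <- numeric(0)
  if (!is.null(ev) && nrow(ev)) {
    if (any(ev$t_emit_s < 0 | ev$t_emit_s > duration_s)) {
      stop("events must lie within the audio duration", call. = FALSE)
    }
    for (k in seq_len(nrow(ev))) {
      src <- c(ev$x[k], ev$y[k], ev$z[k])
      wf <- scene$waveforms[[ev$waveform_id[k]]]
      d <- sqrt(rowSums((mics$positions -
                           rep(src, each = n_ch))^2))
      if (min(d) < 1e-3) {
        stop("event source coincides with a microphone", call. = FALSE)
      }
      p_nearest <- c(p_nearest, mean(wf^2) / min(d)^2)
      for (ch in seq_len(n_ch)) {
        delay <- d[ch] / c_sound
        total <- ev$t_emit_s[k] * fs + delay * fs
        i0 <- floor(total)
        frac <- total - i0
        kern <- frac_delay_kernel(frac)
        xp <- c(rep(0, 32), wf, rep(0, 32))
        y <- as.numeric(stats::filter(xp, kern, method = "convolution",
                                      sides = 2))
        y[is.na(y)] <- 0
        y <- y / d[ch]
        idx <- i0 + seq_along(y) - 32L   # 1-based buffer indices
        keep <- idx >= 1L & idx <= n
        out[ch, idx[keep]] <- out[ch, idx[keep]] + y[keep]
      }
    }
  }
  sigma <- if (!is.null(noise_rms)) noise_rms
           else if (length(p_nearest)) {
             sqrt(stats::median(p_nearest) / 10^(snr_db / 10))
           } else 0
  if (sigma > 0) {
    out <- out + matrix(stats::rnorm(n_ch * n, 0, sigma), n_ch, n)
  }
  audio_block(out, fs, 0)
}

#' Simulate a complete synthetic scene
#'
#' Generates trajectories, draws call events from each bird (Poisson in
#' time, thinned to a minimum inter-event gap so events are separable by
#' the detector), attaches one synthetic call type per bird, and optionally
#' renders the microphone-array audio. Every truth event's source position
#' is the emitting bird's position at the emission frame.
#'
#' @param config an [arena_config()].
#' @param n_individuals number of birds.
#' @param duration_s scene duration (s).
#' @param call_rate_hz per-bird call rate (calls/s). The desk-scale default
#'   (0.05) is deliberately denser than a real aviary day so that short
#'   renders contain enough calls to analyze.
#' @param snr_db rendered SNR at the nearest mic, dB.
#' @param regime_params see [simulate_trajectories()].
#' @param render render audio (set `FALSE` to skip the expensive step).
#' @param min_call_gap_s minimum gap between consecutive events.
#' @return object of class `scene`: list with `trajectories`, `events`
#'   (data.frame `id`, `t_emit_s`, `x`, `y`, `z`, `waveform_id`),
#'   `waveforms`, `audio` (or NULL), `config`.
#' @export
simulate_scene <- function(config, n_individuals = 4L, duration_s = 30,
                           call_rate_hz = 0.05, snr_db = 20,
                           regime_params = list(), render = TRUE,
                           min_call_gap_s = 0.35) {
  trajs <- simulate_trajectories(config, n_individuals, duration_s,
                                 regime_params)
  rate <- config$frame_rate_hz
  with_seed(config$seed + 1L, {
    waveforms <- list()
    events <- NULL
    for (i in seq_len(n_individuals)) {
      wid <- sprintf("call%02d", i)
      waveforms[[wid]] <- synth_call_waveform(
        f0_hz = stats::runif(1, 1800, 2600),
        n_harmonics = sample(1:3, 1),
        duration_s = min(max(stats::rnorm(1, 0.18, 0.04), 0.08), 0.3),
        chirp_rate_hz_s = stats::runif(1, -2000, 2000),
        fs_hz = config$audio_fs_hz)
      n_calls <- stats::rpois(1, call_rate_hz * max(duration_s - 1, 0))
      if (n_calls == 0) next
      t_emit <- sort(stats::runif(n_calls, 0.5, duration_s - 0.6))
      tr <- trajs[[i]]
      fr <- pmin(pmax(round(t_emit * rate) + 1L, 1L), length(tr$time_s))
      events <- rbind(events, data.frame(
        id = as.character(tr$id), t_emit_s = tr$time_s[fr],
        x = tr$positions[fr, 1], y = tr$positions[fr, 2],
        z = tr$positions[fr, 3], waveform_id = wid,
        stringsAsFactors = FALSE))
    }
    if (is.null(events)) {
      events <- data.frame(id = character(0), t_emit_s = numeric(0),
                           x = numeric(0), y = numeric(0), z = numeric(0),
                           waveform_id = character(0),
                           stringsAsFactors = FALSE)
    } else {
      events <- events[order(events$t_emit_s), ]
      keep <- c(TRUE, diff(events$t_emit_s) >= min_call_gap_s)
      while (!all(keep)) {
        events <- events[keep, , drop = FALSE]
        keep <- c(TRUE, diff(events$t_emit_s) >= min_call_gap_s)
      }
      rownames(events) <- NULL
    }
    scene <- structure(list(trajectories = trajs, events = events,
                            waveforms = waveforms, audio = NULL,
                            config = config), class = "scene")
    if (render) {
      mics <- mic_array(config$mic_positions, config$audio_fs_hz,
                        speed_of_sound_m_s = config$speed_of_sound_m_s)
      scene$audio <- render_audio(scene, mics, snr_db = snr_db,
                                  duration_s = duration_s)
    }
    scene
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d birds, %d truth events, audio: %s\n",
              length(x$trajectories), nrow(x$events),
              if (is.null(x$audio)) "not rendered"
              else sprintf("%d ch x %.1f s", nrow(x$audio$samples),
                           ncol(x$audio$samples) / x$audio$fs_hz)))
  invisible(x)
}
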