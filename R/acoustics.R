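# Acoustic event detection, TOAD estimation by cross-correlation, and
# over-determined multilateration with jackknife (leave-one-receiver-out)
# error estimation.

#' Microphone array
#'
#' @param positions n x 3 matrix of receiver positions (m, acoustic frame).
#' @param fs_hz sample rate of the acquisition system (Hz).
#' @param ids optional receiver identifiers (default 1..n).
#' @param speed_of_sound_m_s speed of sound (m/s).
#' @return object of class `mic_array`.
#' @export
mic_array <- function(positions, fs_hz, ids = NULL,
                      speed_of_sound_m_s = 343.0) {
  positions <- as_points3(positions)
  stopifnot_scalar_num(fs_hz, "fs_hz", positive = TRUE)
  stopifnot_scalar_num(speed_of_sound_m_s, "speed_of_sound_m_s",
                       positive = TRUE)
  n <- nrow(positions)
  if (n >= 2L) {
    d <- pairwise_dist(positions, positions)
    if (min(d[upper.tri(d)]) < 1e-9) {
      stop("microphone positions must be distinct", call. = FALSE)
    }
  }
  structure(list(ids = ids %||% seq_len(n), positions = positions,
                 fs_hz = fs_hz, speed_of_sound_m_s = speed_of_sound_m_s),
            class = "mic_array")
}

#' @export
print.mic_array <- function(x, ...) {
  cat(sprintf("<mic_array> %d receivers, fs %g kHz, c = %g m/s\n",
              nrow(x$positions), x$fs_hz / 1000, x$speed_of_sound_m_s))
  invisible(x)
}

#' Multichannel audio block
#'
#' @param samples channels x samples numeric matrix.
#' @param fs_hz sample rate (Hz).
#' @param start_time_s absolute time of the first sample (s).
#' @return object of class `audio_block`.
#' @export
audio_block <- function(samples, fs_hz, start_time_s = 0) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  stopifnot_scalar_num(fs_hz, "fs_hz", positive = TRUE)
  structure(list(samples = samples, fs_hz = fs_hz,
                 start_time_s = start_time_s), class = "audio_block")
}

#' @export
print.audio_block <- function(x, ...) {
  cat(sprintf("<audio_block> %d ch x %d samples @ %g kHz (%.2f s from t = %g)\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz / 1000,
              ncol(x$samples) / x$fs_hz, x$start_time_s))
  invisible(x)
}

# absolute time -> sample index (1-based), clamped to the block
time_to_index <- function(audio, t) {
  i <- round((t - audio$start_time_s) * audio$fs_hz) + 1L
  pmin(pmax(i, 1L), ncol(audio$samples))
}

#' Zero-phase band-pass filter
#'
#' Filters every channel in the frequency domain with a real, symmetric
#' raised-cosine band mask, which is zero-phase by construction and preserves
#' signal length. `low_hz = 0` means no lower edge (low-pass only).
#'
#' @param audio an [audio_block()].
#' @param low_hz,high_hz band edges (Hz), `0 <= low < high < fs/2`.
#' @param transition_hz width of the raised-cosine transition band (Hz).
#' @return filtered [audio_block()].
#' @export
bandpass_filter <- function(audio, low_hz, high_hz,
                            transition_hz = max(0.05 * (high_hz - low_hz), 1)) {
  fs <- audio$fs_hz
  if (!is.finite(low_hz) || !is.finite(high_hz) || low_hz < 0 ||
      low_hz >= high_hz || high_hz >= fs / 2) {
    stop("invalid band: need 0 <= low < high < fs/2", call. = FALSE)
  }
  x <- audio$samples
  n <- ncol(x)
  if (n == 0L) return(audio)
  nfft <- stats::nextn(n, c(2, 3, 5))
  f <- seq(0, nfft - 1) / nfft * fs
  f <- pmin(f, fs - f)                       # two-sided -> folded frequency
  gain <- rep(1, nfft)
  if (low_hz > 0) {
    lo0 <- max(low_hz - transition_hz, 0)
    ramp <- f < low_hz
    gain[ramp] <- 0.5 * (1 - cos(pi * pmax(f[ramp] - lo0, 0) /
                                   (low_hz - lo0)))
  }
  hi1 <- high_hz + transition_hz
  ramp <- f > high_hz
  gain[ramp] <- 0.5 * (1 + cos(pi * pmin(f[ramp] - high_hz, transition_hz) /
                                 transition_hz))
  gain[f > hi1] <- 0
  y <- x
  for (ch in seq_len(nrow(x))) {
    X <- stats::fft(c(x[ch, ], rep(0, nfft - n)))
    y[ch, ] <- Re(stats::fft(X * gain, inverse = TRUE))[seq_len(n)] / nfft
  }
  audio_block(y, fs, audio$start_time_s)
}

#' Detect acoustic events on one channel
#'
#' An energy-envelope detector: the squared signal is smoothed over
#' `window_s`, and samples whose envelope exceeds `median + k * MAD` are
#' event candidates. Candidate runs closer than `merge_gap_s` are fused and
#' runs shorter than `min_duration_s` are dropped.
#'
#' @param audio an [audio_block()] (band-pass filtered upstream).
#' @param channel channel index to run the detector on.
#' @param window_s envelope smoothing window (s).
#' @param k threshold factor on the MAD.
#' @param min_duration_s minimum event duration (s).
#' @param merge_gap_s events separated by less than this are fused (s).
#' @return data.frame with `t_start_s`, `t_end_s` (absolute seconds), sorted
#'   and non-overlapping; zero rows if nothing is detected.
#' @export
detect_events <- function(audio, channel = 1L, window_s = 0.005, k = 8,
                          min_duration_s = 0.01, merge_gap_s = 0.01) {
  x <- audio$samples[channel, ]
  empty <- data.frame(t_start_s = numeric(0), t_end_s = numeric(0))
  if (length(x) == 0L) return(empty)
  fs <- audio$fs_hz
  w <- max(1L, round(window_s * fs))
  env <- moving_sum_centered(x^2, w) / w
  thr <- stats::median(env) + k * stats::mad(env)
  above <- env > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  # fuse runs separated by less than merge_gap
  gap <- round(merge_gap_s * fs)
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1L) {
    for (i in 2:nrow(seg)) {
      if (seg[i, 1] - merged[nrow(merged), 2] < gap) {
        merged[nrow(merged), 2] <- seg[i, 2]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }
  keep <- (merged[, 2] - merged[, 1] + 1L) >= round(min_duration_s * fs)
  merged <- merged[keep, , drop = FALSE]
  data.frame(
    t_start_s = audio$start_time_s + (merged[, 1] - 1L) / fs,
    t_end_s = audio$start_time_s + (merged[, 2] - 1L) / fs)
}

event_window <- function(audio, event) {
  i0 <- time_to_index(audio, event$t_start_s)
  i1 <- time_to_index(audio, event$t_end_s)
  c(i0, i1)
}

#' Per-channel signal-to-noise ratio of an event
#'
#' SNR is defined as `10 log10(P_event / P_noise)` where `P_event` is the
#' mean square in the event window and `P_noise` the mean square in the
#' adjacent pre-event window of equal length (both on the band-passed
#' signal).
#'
#' @param audio an [audio_block()].
#' @param event list/row with `t_start_s`, `t_end_s`.
#' @param channel channel index.
#' @return SNR in dB.
#' @export
compute_snr <- function(audio, event, channel = 1L) {
  w <- event_window(audio, event)
  len <- w[2] - w[1] + 1L
  if (w[1] - len < 1L) {
    stop("no pre-event noise window of equal length exists", call. = FALSE)
  }
  x <- audio$samples[channel, ]
  p_ev <- mean(x[w[1]:w[2]]^2)
  p_no <- mean(x[(w[1] - len):(w[1] - 1L)]^2)
  if (p_no <= 0) stop("noise window has zero power", call. = FALSE)
  10 * log10(p_ev / p_no)
}

#' Select channels for localization
#'
#' Keeps channels whose event-band SNR is at least `min_snr_db`; if fewer
#' than `min_channels` qualify, the top `min_channels` by SNR are returned
#' instead.
#'
#' @param audio an [audio_block()].
#' @param event event with `t_start_s`, `t_end_s`.
#' @param min_snr_db SNR admission threshold (dB).
#' @param min_channels minimum number of channels to return.
#' @return integer channel indices, sorted by decreasing SNR.
#' @export
select_channels <- function(audio, event, min_snr_db = 6, min_channels = 8L) {
  n_ch <- nrow(audio$samples)
  snr <- vapply(seq_len(n_ch), function(ch) {
    tryCatch(compute_snr(audio, event, ch), error = function(e) -Inf)
  }, numeric(1))
  ord <- order(snr, decreasing = TRUE)
  pass <- ord[snr[ord] >= min_snr_db]
  if (length(pass) < min_channels) pass <- ord[seq_len(min(min_channels, n_ch))]
  pass
}

#' Estimate time-of-arrival differences by cross-correlation
#'
#' Cross-correlates each channel against the reference channel over the
#' event window (padded by `max_lag_s`) and refines the correlation peak
#' with a 3-point parabolic interpolation. Positive delays mean the channel
#' receives the signal later than the reference. Ties between equal
#' correlation peaks are broken toward the smaller absolute delay.
#'
#' @param audio an [audio_block()].
#' @param event event with `t_start_s`, `t_end_s`.
#' @param channels channel indices to use.
#' @param ref_channel reference channel; default the loudest (max event RMS)
#'   among `channels`.
#' @param max_lag_s physical search range for delays (s).
#' @param phat use PHAT (phase transform) weighting instead of plain
#'   cross-correlation.
#' @return named numeric vector of delays (s), one per `channels`, with the
#'   reference entry exactly 0; attribute `ref_channel`.
#' @export
estimate_toads <- function(audio, event, channels,
                           ref_channel = NULL, max_lag_s = 0.06,
                           phat = FALSE) {
  if (length(channels) < 2L) stop("need at least 2 channels", call. = FALSE)
  fs <- audio$fs_hz
  w <- event_window(audio, event)
  pad <- ceiling(max_lag_s * fs)
  i0 <- max(w[1] - pad, 1L)
  i1 <- min(w[2] + pad, ncol(audio$samples))
  seg <- audio$samples[channels, i0:i1, drop = FALSE]
  if (is.null(ref_channel)) {
    ev_rel <- (w[1]:w[2]) - i0 + 1L
    rms <- sqrt(rowMeans(seg[, ev_rel, drop = FALSE]^2))
    ref_channel <- channels[which.max(rms)]
  }
  if (!ref_channel %in% channels) {
    stop("ref_channel must be among the selected channels", call. = FALSE)
  }
  n <- ncol(seg)
  nfft <- stats::nextn(2L * n, c(2, 3, 5))
  ref_row <- match(ref_channel, channels)
  A <- stats::fft(c(seg[ref_row, ], rep(0, nfft - n)))
  max_lag <- pad
  taus <- vapply(seq_along(channels), function(j) {
    if (j == ref_row) return(0)
    B <- stats::fft(c(seg[j, ], rep(0, nfft - n)))
    S <- Conj(A) * B
    if (phat) {
      # whiten only where the cross-spectrum carries energy, else the
      # transform amplifies out-of-band noise into spurious peaks
      m <- Mod(S)
      keep <- m > 1e-3 * max(m)
      S[keep] <- S[keep] / m[keep]
      S[!keep] <- 0
    }
    cc <- Re(stats::fft(S, inverse = TRUE)) / nfft
    # lag k: channel j delayed by k samples relative to reference
    lags <- c(0:max_lag, -(max_lag:1))
    idx <- c(seq_len(max_lag + 1L), nfft - (max_lag:1) + 1L)
    cv <- cc[idx]
    if (max(abs(cv)) < 1e-300) {
      stop("flat cross-correlation (zero signal) on channel ",
           channels[j], call. = FALSE)
    }
    peak <- max(cv)
    cand <- which(cv >= peak * (1 - 1e-12))
    best <- cand[which.min(abs(lags[cand]))]
    lag <- lags[best]
    # 3-point parabolic sub-sample refinement
    km <- which(lags == lag - 1L); kp <- which(lags == lag + 1L)
    delta <- 0
    if (length(km) == 1L && length(kp) == 1L) {
      y1 <- cv[km]; y2 <- cv[best]; y3 <- cv[kp]
      den <- y1 - 2 * y2 + y3
      if (abs(den) > 1e-300) delta <- 0.5 * (y1 - y3) / den
      if (!is.finite(delta) || abs(delta) > 1) delta <- 0
    }
    (lag + delta) / fs
  }, numeric(1))
  names(taus) <- channels
  attr(taus, "ref_channel") <- ref_channel
  taus
}

toad_residuals <- function(x, pos, ref, taus, c_sound) {
  d <- sqrt(colSums((t(pos) - x)^2))
  (d - d[ref]) / c_sound - taus
}

#' Localize a sound source from TOADs by bounded least squares
#'
#' Minimizes the sum of squared TOAD residuals
#' `((|x - m_i| - |x - m_ref|)/c - tau_i)^2` over the arena box. The
#' optimization is seeded from the best node of a coarse grid, refined with
#' bounded L-BFGS-B, and polished with a few Gauss-Newton steps when the
#' solution is interior.
#'
#' @param toads delay vector (s) as returned by [estimate_toads()]; the
#'   entry equal to 0 marks the reference receiver (or pass `ref`).
#' @param mics a [mic_array()] whose rows align with `toads`.
#' @param bounds 2 x 3 matrix (rows lower/upper) of the search box; e.g.
#'   [arena_bounds()] of the arena config.
#' @param ref index of the reference receiver within `toads`.
#' @param grid_step_m coarse grid spacing for the seed (m).
#' @return list with `position` (3-vector), `residual_rms_s`, `residuals`
#'   (per-channel, s), `at_bounds` flag.
#' @export
localize_source <- function(toads, mics, bounds, ref = NULL,
                            grid_step_m = 0.5) {
  pos <- mics$positions
  n <- length(toads)
  if (n < 4L) stop("need at least 4 receivers for 3D localization",
                   call. = FALSE)
  if (nrow(pos) != n) stop("toads and mic positions disagree in length",
                           call. = FALSE)
  if (!all(is.finite(toads))) stop("TOADs must be finite", call. = FALSE)
  if (is.null(ref)) {
    ref <- which(toads == 0)[1]
    if (is.na(ref)) stop("no zero entry in toads; pass `ref`", call. = FALSE)
  }
  c_sound <- mics$speed_of_sound_m_s
  lower <- bounds[1, ]; upper <- bounds[2, ]
  cost <- function(x) sum(toad_residuals(x, pos, ref, toads, c_sound)^2)
  grad <- function(x) {
    dif <- t(pos) - x                       # 3 x n (mic - x)
    d <- sqrt(colSums(dif^2))
    u <- -t(dif) / d                        # n x 3 unit vectors x - m_i
    r <- (d - d[ref]) / c_sound - toads
    as.numeric(2 / c_sound * colSums(r * (u - rep(u[ref, ], each = n))))
  }
  # coarse grid seed
  gx <- seq(lower[1], upper[1], by = grid_step_m)
  gy <- seq(lower[2], upper[2], by = grid_step_m)
  gz <- seq(lower[3], upper[3], by = grid_step_m)
  grid <- as.matrix(expand.grid(gx, gy, gz))
  D <- pairwise_dist(grid, pos)
  R <- (D - D[, ref]) / c_sound - rep(toads, each = nrow(grid))
  seed <- grid[which.min(rowSums(R^2)), ]
  fit <- stats::optim(seed, cost, grad, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 10, pgtol = 1e-14, maxit = 500))
  x <- fit$par
  tol <- 1e-9
  interior <- all(x > lower + tol & x < upper - tol)
  if (interior) {
    # Gauss-Newton polish (quadratic convergence near the optimum)
    for (it in 1:12) {
      dif <- t(pos) - x
      d <- sqrt(colSums(dif^2))
      u <- -t(dif) / d
      r <- (d - d[ref]) / c_sound - toads
      J <- (u - rep(u[ref, ], each = n)) / c_sound
      step <- tryCatch(solve(crossprod(J) + diag(1e-15, 3), -crossprod(J, r)),
                       error = function(e) NULL)
      if (is.null(step)) break
      xn <- pmin(pmax(x + as.numeric(step), lower), upper)
      if (cost(xn) <= cost(x)) x <- xn else break
      if (sqrt(sum(step^2)) < 1e-12) break
    }
    interior <- all(x > lower + tol & x < upper - tol)
  }
  res <- toad_residuals(x, pos, ref, toads, c_sound)
  list(position = as.numeric(x),
       residual_rms_s = sqrt(mean(res[-ref]^2)),
       residuals = res,
       at_bounds = !interior)
}

#' Jackknife localization spread
#'
#' Re-localizes the source leaving each receiver out once and reports the
#' RMS distance of the leave-one-out solutions from their centroid. This is
#' the relative localization error afforded by an over-determined array.
#'
#' @inheritParams localize_source
#' @return spread in meters; attribute `solutions` holds the leave-one-out
#'   position matrix.
#' @export
jackknife_error <- function(toads, mics, bounds, ref = NULL,
                            grid_step_m = 0.5) {
  n <- length(toads)
  if (n < 5L) stop("jackknife needs at least 5 receivers", call. = FALSE)
  if (is.null(ref)) ref <- which(toads == 0)[1]
  sols <- matrix(NA_real_, n, 3)
  for (drop in seq_len(n)) {
    keep <- setdiff(seq_len(n), drop)
    tk <- toads[keep]
    rk <- if (drop == ref) {
      tk <- tk - tk[1]                       # re-reference to first kept
      1L
    } else {
      match(ref, keep)
    }
    sub <- mic_array(mics$positions[keep, , drop = FALSE], mics$fs_hz,
                     speed_of_sound_m_s = mics$speed_of_sound_m_s)
    sols[drop, ] <- localize_source(tk, sub, bounds, ref = rk,
                                    grid_step_m = grid_step_m)$position
  }
  centroid <- colMeans(sols)
  spread <- sqrt(mean(rowSums((sols - rep(centroid, each = n))^2)))
  attr(spread, "solutions") <- sols
  spread
}
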