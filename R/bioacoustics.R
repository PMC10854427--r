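# Bioacoustic spectral features, PCA embedding, and assignment of localized
# sounds to arena zones and to individuals.

# discrete cumulative-power quantile: first bin whose cumulative power
# reaches fraction `q` (bin-resolution, as in standard bioacoustic tools)
cum_power_quantile <- function(freqs, power, q) {
  cs <- cumsum(power)
  freqs[which(cs >= q * cs[length(cs)])[1]]
}

stft_mat <- function(x, fs, n = 512L, overlap = 0.75) {
  hop <- max(1L, round(n * (1 - overlap)))
  if (length(x) < n) {
    x <- c(x, rep(0, n - length(x)))
  }
  starts <- seq(1L, length(x) - n + 1L, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))   # Hann
  nb <- n %/% 2L + 1L
  P <- vapply(starts, function(s) {
    X <- stats::fft(x[s:(s + n - 1L)] * win)
    Mod(X[seq_len(nb)])^2
  }, numeric(nb))
  list(power = P,                                  # bins x frames
       freqs = (seq_len(nb) - 1L) * fs / n,
       times = (starts - 1L + n / 2) / fs)
}

#' Spectral features of a sound clip
#'
#' Measures the standard call descriptors on the clip's power spectrum and
#' energy envelope:
#' * peak frequency: frequency with the most power;
#' * center frequency: frequency below which half of the power falls;
#' * 90% bandwidth: `f(95%) - f(5%)` of cumulative spectral power;
#' * 90% duration: time between the 5% and 95% cumulative-energy points;
#' * inflection points: slope sign changes of the per-frame peak-frequency
#'   contour (512-sample Hann STFT, 75% overlap, 3-frame median smoothed);
#' * aggregate entropy: Shannon entropy (bits) of the normalized mean
#'   spectrum.
#'
#' @param clip numeric waveform.
#' @param fs_hz sample rate (Hz).
#' @param stft_n STFT window (samples).
#' @param stft_overlap STFT overlap fraction.
#' @return list of class `spectral_features`.
#' @export
spectral_features <- function(clip, fs_hz, stft_n = 512L,
                              stft_overlap = 0.75) {
  clip <- as.numeric(clip)
  if (length(clip) == 0L || all(clip == 0)) {
    stop("clip is silent: no spectral features", call. = FALSE)
  }
  n <- length(clip)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))
  X <- stats::fft(clip * win)
  nb <- n %/% 2L + 1L
  power <- Mod(X[seq_len(nb)])^2
  freqs <- (seq_len(nb) - 1L) * fs_hz / n
  peak <- freqs[which.max(power)]
  center <- cum_power_quantile(freqs, power, 0.5)
  bw90 <- cum_power_quantile(freqs, power, 0.95) -
    cum_power_quantile(freqs, power, 0.05)
  # 90% energy duration from the cumulative squared signal
  tt <- (seq_len(n) - 1L) / fs_hz
  dur90 <- cum_power_quantile(tt, clip^2, 0.95) -
    cum_power_quantile(tt, clip^2, 0.05)
  # peak-frequency contour
  S <- stft_mat(clip, fs_hz, stft_n, stft_overlap)
  fe <- colSums(S$power)
  use <- fe > 1e-4 * max(fe)
  contour <- S$freqs[apply(S$power[, use, drop = FALSE], 2, which.max)]
  if (length(contour) >= 3L) {
    contour <- stats::runmed(contour, 3)
  }
  slope <- diff(contour)
  slope <- slope[slope != 0]
  inflections <- if (length(slope) >= 2L) {
    sum(diff(sign(slope)) != 0)
  } else 0L
  # aggregate entropy of the normalized mean spectrum
  ms <- rowMeans(S$power[, use, drop = FALSE])
  p <- ms / sum(ms)
  p <- p[p > 0]
  entropy <- -sum(p * log2(p))
  structure(list(peak_frequency_hz = peak, center_frequency_hz = center,
                 bandwidth90_hz = bw90, duration90_s = dur90,
                 inflection_points = inflections,
                 aggregate_entropy_bits = entropy),
            class = "spectral_features")
}

#' @export
print.spectral_features <- function(x, ...) {
  cat(sprintf(
    "<spectral_features> peak %.0f Hz, center %.0f Hz, bw90 %.0f Hz, dur90 %.3f s, %d inflections, %.2f bits\n",
    x$peak_frequency_hz, x$center_frequency_hz, x$bandwidth90_hz,
    x$duration90_s, x$inflection_points, x$aggregate_entropy_bits))
  invisible(x)
}

#' Pick the loudest channel for an event
#'
#' Channel with the maximum RMS in the event window; ties break to the
#' lowest channel index.
#'
#' @param audio an [audio_block()].
#' @param event event with `t_start_s`, `t_end_s`.
#' @return channel index.
#' @export
pick_loudest_channel <- function(audio, event) {
  w <- event_window(audio, event)
  seg <- audio$samples[, w[1]:w[2], drop = FALSE]
  which.max(sqrt(rowMeans(seg^2)))
}

#' PCA embedding of a feature matrix
#'
#' Z-scores the features, drops constant columns with a warning, and runs a
#' principal components analysis.
#'
#' @param features numeric matrix or data.frame (rows = sounds).
#' @param n_components number of components to keep (default all).
#' @return list with `scores`, `loadings`, `explained_variance`
#'   (proportions, non-increasing) and `sdev`.
#' @export
pca_embed <- function(features, n_components = NULL) {
  X <- as.matrix(features)
  if (nrow(X) < 2L) stop("need at least 2 rows for PCA", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- min(n_components %||% ncol(p$x), ncol(p$x))
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)], sdev = p$sdev[seq_len(k)])
}

#' Assign a 3D position to an arena zone
#'
#' Zones follow the floor plan: foraging for low positions over the
#' foraging region, perching for mid-height positions over the perch
#' region, flight elsewhere inside the arena; positions outside the arena
#' box are flagged `"outside"`.
#'
#' @param position 3-vector (m, global frame).
#' @param zone_plan zone plan from [arena_config()] (needs
#'   `foraging_polygon`, `perch_polygon`, `z_low`, `z_high`).
#' @param arena_box optional 2 x 3 bounds matrix (rows lower/upper).
#' @return one of `"foraging"`, `"perching"`, `"flight"`, `"outside"`.
#' @export
assign_zone <- function(position, zone_plan, arena_box = NULL) {
  p <- vec3(position)
  if (!is.null(arena_box)) {
    if (any(p < arena_box[1, ]) || any(p > arena_box[2, ])) return("outside")
  }
  if (p[3] < zone_plan$z_low &&
      point_in_polygon(p[1], p[2], zone_plan$foraging_polygon)) {
    return("foraging")
  }
  if (p[3] < zone_plan$z_high &&
      point_in_polygon(p[1], p[2], zone_plan$perch_polygon)) {
    return("perching")
  }
  "flight"
}

#' Assign a localized sound to an individual
#'
#' Interpolates every track to the event's midpoint time and assigns the
#' sound to the closest individual iff (i) that individual is within
#' `d_max_m` and (ii) the next closest individual is at least
#' `ratio` times farther away.
#'
#' @param position 3-vector: localized source position (m).
#' @param time_s event midpoint time (s).
#' @param trajs list of [trajectory()]s.
#' @param d_max_m proximity criterion (m), default 0.30.
#' @param ratio next-closest distance ratio criterion, default 1.5.
#' @return list with `id` (or `NA`), `distance_m`, `runner_up_m`, `reason`
#'   (`"assigned"`, `"no-track"`, `"too-far"`, `"ambiguous"`).
#' @export
assign_individual <- function(position, time_s, trajs, d_max_m = 0.30,
                              ratio = 1.5) {
  p <- vec3(position)
  cand <- list()
  for (tr in trajs) {
    t0 <- tr$time_s[1]; t1 <- tr$time_s[length(tr$time_s)]
    if (time_s < t0 - 1e-9 || time_s > t1 + 1e-9) next
    xi <- vapply(1:3, function(k) {
      stats::approx(tr$time_s, tr$positions[, k], xout = time_s,
                    rule = 2)$y
    }, numeric(1))
    cand[[length(cand) + 1L]] <- list(id = tr$id,
                                      d = sqrt(sum((xi - p)^2)))
  }
  if (length(cand) == 0L) {
    return(list(id = NA_character_, distance_m = NA_real_,
                runner_up_m = NA_real_, reason = "no-track"))
  }
  d <- vapply(cand, function(x) x$d, numeric(1))
  ord <- order(d)
  d1 <- d[ord[1]]
  d2 <- if (length(d) >= 2L) d[ord[2]] else Inf
  if (d1 > d_max_m) {
    reason <- "too-far"; id <- NA_character_
  } else if (d2 < ratio * d1) {
    reason <- "ambiguous"; id <- NA_character_
  } else {
    reason <- "assigned"; id <- as.character(cand[[ord[1]]]$id)
  }
  list(id = id, distance_m = d1, runner_up_m = d2, reason = reason)
}
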