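# Arena configuration: geometry, zone plan, microphone layout.

#' Default ceiling microphone layout
#'
#' Places `n` receivers evenly along the perimeter of the ceiling rectangle,
#' inset slightly from the walls, all at `height_m`. The real array is only
#' described as fixed to the top frame, so any perimeter layout is admissible;
#' this one is the package default and is fully configurable.
#'
#' @param length_m,width_m,height_m arena dimensions in meters.
#' @param n number of microphones.
#' @param inset_m distance from the walls, meters.
#' @return n x 3 matrix of microphone positions.
#' @export
default_mic_positions <- function(length_m, width_m, height_m, n = 30L,
                                  inset_m = 0.1) {
  L <- length_m - 2 * inset_m
  W <- width_m - 2 * inset_m
  per <- 2 * (L + W)
  s <- (seq_len(n) - 0.5) / n * per
  xy <- t(vapply(s, function(si) {
    if (si < L) c(si, 0)
    else if (si < L + W) c(L, si - L)
    else if (si < 2 * L + W) c(2 * L + W - si, W)
    else c(0, per - si)
  }, numeric(2)))
  cbind(xy[, 1] + inset_m, xy[, 2] + inset_m, rep(height_m, n))
}

#' Arena configuration
#'
#' Describes the tracking volume, its zone plan (foraging floor region and
#' perch sites), the ceiling microphone array, and the acquisition rates.
#' The defaults reproduce the barn geometry the toolkit was designed around:
#' a 14.68 m x 6.62 m footprint with a 3.83 m ceiling, 100 Hz motion-capture
#' frames and 100 kHz audio.
#'
#' @param length_m,width_m,height_m arena dimensions (m).
#' @param frame_rate_hz motion-capture frame rate (Hz).
#' @param audio_fs_hz audio sample rate (Hz).
#' @param speed_of_sound_m_s speed of sound (m/s).
#' @param mic_positions optional n x 3 matrix; defaults to
#'   [default_mic_positions()] with 30 receivers.
#' @param zone_plan optional list with `foraging_polygon` (k x 2 floor
#'   polygon), `perch_polygon` (k x 2), `perch_positions` (p x 3),
#'   `z_low`, `z_high` (m).
#' @param seed integer seed that fully determines simulator output.
#' @return object of class `arena_config`.
#' @export
arena_config <- function(length_m = 14.68, width_m = 6.62, height_m = 3.83,
                         frame_rate_hz = 100, audio_fs_hz = 100000,
                         speed_of_sound_m_s = 343.0,
                         mic_positions = NULL, zone_plan = NULL, seed = 1L) {
  stopifnot_scalar_num(length_m, "length_m", positive = TRUE)
  stopifnot_scalar_num(width_m, "width_m", positive = TRUE)
  stopifnot_scalar_num(height_m, "height_m", positive = TRUE)
  stopifnot_scalar_num(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  stopifnot_scalar_num(audio_fs_hz, "audio_fs_hz", positive = TRUE)
  stopifnot_scalar_num(speed_of_sound_m_s, "speed_of_sound_m_s", positive = TRUE)
  if (is.null(mic_positions)) {
    mic_positions <- default_mic_positions(length_m, width_m, height_m)
  }
  mic_positions <- as_points3(mic_positions)
  box_ok <- all(mic_positions[, 1] >= 0 & mic_positions[, 1] <= length_m &
                mic_positions[, 2] >= 0 & mic_positions[, 2] <= width_m &
                mic_positions[, 3] >= 0 & mic_positions[, 3] <= height_m)
  if (!box_ok) stop("microphone positions must lie inside the arena box",
                    call. = FALSE)
  if (is.null(zone_plan)) {
    # foraging boxes at the low-x end of the floor, perches at the high-x end
    zone_plan <- list(
      foraging_polygon = rbind(c(0.5, 0.5), c(4.5, 0.5),
                               c(4.5, width_m - 0.5), c(0.5, width_m - 0.5)),
      perch_polygon = rbind(c(length_m - 3.5, 0.5), c(length_m - 0.5, 0.5),
                            c(length_m - 0.5, width_m - 0.5),
                            c(length_m - 3.5, width_m - 0.5)),
      perch_positions = cbind(
        x = rep(length_m - 1.8, 4),
        y = seq(1.2, width_m - 1.2, length.out = 4),
        z = rep(1.5, 4)),
      z_low = 0.5, z_high = 3.0)
  }
  structure(list(
    length_m = length_m, width_m = width_m, height_m = height_m,
    frame_rate_hz = frame_rate_hz, audio_fs_hz = audio_fs_hz,
    speed_of_sound_m_s = speed_of_sound_m_s,
    mic_positions = mic_positions, zone_plan = zone_plan,
    seed = as.integer(seed)), class = "arena_config")
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena_config> %.2f x %.2f x %.2f m, %d mics, %g Hz frames, %g kHz audio, seed %d\n",
              x$length_m, x$width_m, x$height_m, nrow(x$mic_positions),
              x$frame_rate_hz, x$audio_fs_hz / 1000, x$seed))
  invisible(x)
}

#' Search bounds of the arena box
#' @param config an [arena_config()].
#' @return 2 x 3 matrix (rows lower/upper) in meters.
#' @export
arena_bounds <- function(config) {
  rbind(lower = c(0, 0, 0),
        upper = c(config$length_m, config$width_m, config$height_m))
}
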