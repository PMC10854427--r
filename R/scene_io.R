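# Scene serialization: plain-text tracks/mics/labels CSV, truth-event JSON,
# float32 WAV audio, full-precision JSON config. Round-trips are bit-exact
# for the CSV/JSON fields and float32-exact for audio.

fmt_full <- function(x) sprintf("%.17g", x)

write_tracks_csv <- function(trajs, path) {
  rows <- lapply(trajs, function(tr) {
    n <- length(tr$time_s)
    df <- data.frame(frame = 0:(n - 1L), time_s = fmt_full(tr$time_s),
                     id = as.character(tr$id),
                     x_m = fmt_full(tr$positions[, 1]),
                     y_m = fmt_full(tr$positions[, 2]),
                     z_m = fmt_full(tr$positions[, 3]),
                     stringsAsFactors = FALSE)
    if (!is.null(tr$quaternions)) {
      df$qw <- fmt_full(tr$quaternions[, 1])
      df$qx <- fmt_full(tr$quaternions[, 2])
      df$qy <- fmt_full(tr$quaternions[, 3])
      df$qz <- fmt_full(tr$quaternions[, 4])
    }
    df
  })
  has_q <- vapply(rows, function(r) "qw" %in% names(r), logical(1))
  if (any(has_q) && !all(has_q)) {
    rows <- lapply(rows, function(r) {
      if (!"qw" %in% names(r)) r[c("qw", "qx", "qy", "qz")] <- ""
      r
    })
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a 3D track table
#'
#' CSV with columns `frame,time_s,id,x_m,y_m,z_m` and optional unit
#' quaternions `qw,qx,qy,qz`.
#'
#' @param path CSV path.
#' @param frame_rate_hz optional frame rate override.
#' @return list of [trajectory()], one per `id`.
#' @export
read_tracks_csv <- function(path, frame_rate_hz = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "id", "x_m", "y_m", "z_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("track CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  lapply(split(df, df$id), function(d) {
    d <- d[order(d$frame), ]
    q <- if (all(c("qw", "qx", "qy", "qz") %in% names(d)) &&
             !all(is.na(suppressWarnings(as.numeric(d$qw))))) {
      cbind(as.numeric(d$qw), as.numeric(d$qx),
            as.numeric(d$qy), as.numeric(d$qz))
    } else NULL
    trajectory(d$id[1], as.numeric(d$time_s),
               cbind(as.numeric(d$x_m), as.numeric(d$y_m),
                     as.numeric(d$z_m)),
               quaternions = q, frame_rate_hz = frame_rate_hz)
  })
}

#' Read / write a microphone geometry table
#'
#' CSV with columns `id,x,y,z` (meters).
#' @param path CSV path.
#' @param positions n x 3 matrix (write).
#' @param ids receiver ids (write).
#' @return matrix of positions with `ids` attribute (read).
#' @export
read_mics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("mic CSV needs columns id,x,y,z", call. = FALSE)
  }
  m <- cbind(as.numeric(df$x), as.numeric(df$y), as.numeric(df$z))
  attr(m, "ids") <- df$id
  m
}

#' @rdname read_mics_csv
#' @export
write_mics_csv <- function(positions, path, ids = NULL) {
  positions <- as_points3(positions)
  utils::write.csv(
    data.frame(id = ids %||% seq_len(nrow(positions)),
               x = fmt_full(positions[, 1]), y = fmt_full(positions[, 2]),
               z = fmt_full(positions[, 3])),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scene to a directory / read it back
#'
#' Layout: `tracks.csv` (track table), `labels.csv` (ground-truth regime per
#' frame), `mics.csv`, `events_truth.json`, `config.json` (full precision),
#' `audio.wav` (float32) and `waveforms/<id>.wav`.
#'
#' @param scene a [simulate_scene()] scene.
#' @param directory output directory (created if needed).
#' @return the directory (write) or the reconstructed scene (read).
#' @export
write_scene <- function(scene, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  cfg <- scene$config
  write_tracks_csv(scene$trajectories, file.path(directory, "tracks.csv"))
  labs <- do.call(rbind, lapply(scene$trajectories, function(tr) {
    if (is.null(tr$behavior)) return(NULL)
    data.frame(frame = seq_along(tr$time_s) - 1L, id = as.character(tr$id),
               label = tr$behavior, stringsAsFactors = FALSE)
  }))
  if (!is.null(labs)) {
    utils::write.csv(labs, file.path(directory, "labels.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  write_mics_csv(cfg$mic_positions, file.path(directory, "mics.csv"))
  jsonlite::write_json(scene$events, file.path(directory, "events_truth.json"),
                       dataframe = "rows", digits = I(17))
  cfg_out <- cfg
  cfg_out$mic_positions <- unclass(cfg_out$mic_positions)
  jsonlite::write_json(unclass(cfg_out), file.path(directory, "config.json"),
                       auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  if (!is.null(scene$audio)) {
    write_wav(scene$audio$samples, file.path(directory, "audio.wav"),
              scene$audio$fs_hz)
  }
  if (length(scene$waveforms)) {
    wdir <- file.path(directory, "waveforms")
    dir.create(wdir, showWarnings = FALSE)
    for (wid in names(scene$waveforms)) {
      write_wav(scene$waveforms[[wid]], file.path(wdir, paste0(wid, ".wav")),
                cfg$audio_fs_hz)
    }
  }
  invisible(directory)
}

#' @rdname write_scene
#' @export
read_scene <- function(directory) {
  need <- function(f) {
    p <- file.path(directory, f)
    if (!file.exists(p)) {
      stop("scene directory is missing required file: ", f, call. = FALSE)
    }
    p
  }
  cfg_raw <- jsonlite::read_json(need("config.json"), simplifyVector = TRUE)
  config <- arena_config(
    length_m = cfg_raw$length_m, width_m = cfg_raw$width_m,
    height_m = cfg_raw$height_m, frame_rate_hz = cfg_raw$frame_rate_hz,
    audio_fs_hz = cfg_raw$audio_fs_hz,
    speed_of_sound_m_s = cfg_raw$speed_of_sound_m_s,
    mic_positions = cfg_raw$mic_positions,
    zone_plan = list(
      foraging_polygon = cfg_raw$zone_plan$foraging_polygon,
      perch_polygon = cfg_raw$zone_plan$perch_polygon,
      perch_positions = cfg_raw$zone_plan$perch_positions,
      z_low = cfg_raw$zone_plan$z_low, z_high = cfg_raw$zone_plan$z_high),
    seed = cfg_raw$seed)
  trajs <- read_tracks_csv(need("tracks.csv"),
                           frame_rate_hz = config$frame_rate_hz)
  lab_path <- file.path(directory, "labels.csv")
  if (file.exists(lab_path)) {
    labs <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
    for (id in names(trajs)) {
      li <- labs[labs$id == id, ]
      if (nrow(li)) trajs[[id]]$behavior <- li$label[order(li$frame)]
    }
  }
  events <- jsonlite::read_json(need("events_truth.json"),
                                simplifyVector = TRUE)
  if (length(events) == 0L) {
    events <- data.frame(id = character(0), t_emit_s = numeric(0),
                         x = numeric(0), y = numeric(0), z = numeric(0),
                         waveform_id = character(0), stringsAsFactors = FALSE)
  }
  wdir <- file.path(directory, "waveforms")
  waveforms <- list()
  if (dir.exists(wdir)) {
    for (f in list.files(wdir, pattern = "\\.wav$")) {
      waveforms[[sub("\\.wav$", "", f)]] <-
        as.numeric(read_wav(file.path(wdir, f))$samples)
    }
  }
  audio <- NULL
  apath <- file.path(directory, "audio.wav")
  if (file.exists(apath)) {
    w <- read_wav(apath)
    audio <- audio_block(w$samples, w$fs_hz, 0)
  }
  # restore trajectory order by id
  trajs <- trajs[order(names(trajs))]
  structure(list(trajectories = trajs, events = events,
                 waveforms = waveforms, audio = audio, config = config),
            class = "scene")
}
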