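# synthetic_data: trajectories, call waveforms, audio rendering, scene I/O

test_that("perch-only regime stays in the perching class everywhere", {
  cfg <- small_arena(seed = 3)
  trs <- simulate_trajectories(cfg, 2, 20,
                               regime_params = list(regimes = "perch"))
  for (tr in trs) {
    expect_true(all(tr$positions[, 3] >= 0.5 & tr$positions[, 3] < 3))
    expect_true(all(compute_speed(tr) < 1))
    expect_true(all(tr$behavior == "perch"))
  }
})

test_that("noiseless follower reproduces the leader delay (oracle sweep)", {
  rp <- list(regimes = "flight",
             followers = list(list(leader = 1, follower = 2, tau_f = 0.4,
                                   noise = 0)))
  trs <- simulate_trajectories(arena_config(seed = 11), 2, 20, rp)
  vi <- arenatrack:::traj_velocity(trs[[1]])
  vj <- arenatrack:::traj_velocity(trs[[2]])
  lags <- -100:100
  C <- oracle_dir_corr(vi[100:1900, ], vj[100:1900, ], lags)
  best <- lags[which.max(C)]
  expect_lte(abs(best - 40), 1)           # 0.4 s at 100 Hz, +/- one frame
  expect_gt(max(C), 0.99)
})

test_that("simulation is deterministic in the seed", {
  cfg <- small_arena(seed = 17)
  a <- simulate_trajectories(cfg, 3, 10)
  b <- simulate_trajectories(cfg, 3, 10)
  expect_identical(a, b)
  c2 <- simulate_trajectories(small_arena(seed = 18), 3, 10)
  expect_false(identical(a, c2))
})

test_that("trajectory generator validates its inputs", {
  cfg <- small_arena()
  expect_error(simulate_trajectories(cfg, 2, -1), "duration")
  expect_error(simulate_trajectories(cfg, 2, 10,
    regime_params = list(regimes = c("perch", "swim", "flight"))), "swim")
  expect_error(simulate_trajectories(cfg, 2, 5, regime_params = list(
    followers = list(list(leader = 1, follower = 2, tau_f = 9)))), "tau_f")
})

test_that("ground-truth labels agree with the classifier off transitions", {
  cfg <- arena_config(seed = 7)
  trs <- simulate_trajectories(cfg, 3, 60)
  for (tr in trs) {
    s <- classify_behavior(tr)
    truth <- arenatrack:::regime_to_class(tr$behavior)
    trans <- which(c(FALSE, tr$behavior[-1] != tr$behavior[-length(tr$behavior)]))
    margin <- unique(pmax(pmin(as.vector(outer(trans, -50:50, "+")),
                               length(truth)), 1))
    keep <- setdiff(seq_along(truth), margin)
    expect_gte(mean(s$label[keep] == truth[keep]), 0.99)
  }
})

test_that("call synthesis hits its frequency contract and alias guard", {
  fs <- 100000
  wf <- synth_call_waveform(2000, 1, 0.2, 0, fs)
  expect_equal(max(abs(wf)), 1)
  sf <- spectral_features(wf, fs)
  expect_lte(abs(sf$peak_frequency_hz - 2000), fs / length(wf))
  expect_identical(sf$inflection_points, 0L)     # chirp_rate 0: flat contour
  expect_silent(synth_call_waveform(2000, 3, 0.1, 0, fs))
  expect_error(synth_call_waveform(2000, 30, 0.1, 0, fs), "harmonic")
  expect_error(synth_call_waveform(60000, 1, 0.1, 0, fs), "f0")
})

test_that("rendered impulse reproduces geometric TOADs within one sample", {
  cfg <- arena_config(audio_fs_hz = 50000, seed = 3)
  mics <- mic_array(cfg$mic_positions, cfg$audio_fs_hz)
  src <- c(5, 3, 1)
  wf <- synth_call_waveform(2000, 2, 0.1, 0, cfg$audio_fs_hz)
  scene <- structure(list(
    trajectories = list(),
    events = data.frame(id = "b", t_emit_s = 0.3, x = src[1], y = src[2],
                        z = src[3], waveform_id = "w"),
    waveforms = list(w = wf), config = cfg), class = "scene")
  aud <- render_audio(scene, mics, noise_rms = 0, duration_s = 1)
  taus <- estimate_toads(aud, list(t_start_s = 0.3, t_end_s = 0.45), 1:30,
                         ref_channel = 1)
  truth <- geometric_toads(src, mics, ref = 1)
  expect_lt(max(abs(taus - truth)), 1 / cfg$audio_fs_hz)
})

test_that("render respects the noise floor and the requested SNR", {
  cfg <- arena_config(audio_fs_hz = 20000, seed = 5)
  mics <- mic_array(cfg$mic_positions, cfg$audio_fs_hz)
  empty <- structure(list(trajectories = list(),
                          events = data.frame(), waveforms = list(),
                          config = cfg), class = "scene")
  aud <- render_audio(empty, mics, noise_rms = 0.01, duration_s = 2)
  expect_lt(abs(sqrt(mean(aud$samples^2)) / 0.01 - 1), 0.01)

  wf <- synth_call_waveform(2000, 1, 0.15, 0, cfg$audio_fs_hz)
  sc <- structure(list(trajectories = list(),
                       events = data.frame(id = "b", t_emit_s = 1, x = 7,
                                           y = 3, z = 1, waveform_id = "w"),
                       waveforms = list(w = wf), config = cfg),
                  class = "scene")
  aud2 <- render_audio(sc, mics, snr_db = 20, duration_s = 2)
  d <- sqrt(rowSums((mics$positions - rep(c(7, 3, 1), each = 30))^2))
  snr <- compute_snr(aud2, list(t_start_s = 1, t_end_s = 1.15),
                     which.min(d))
  expect_lt(abs(snr - 20), 1)
})

test_that("a source on top of a microphone is rejected", {
  cfg <- arena_config(audio_fs_hz = 20000, seed = 5)
  mics <- mic_array(cfg$mic_positions, cfg$audio_fs_hz)
  m1 <- cfg$mic_positions[1, ]
  sc <- structure(list(trajectories = list(),
                       events = data.frame(id = "b", t_emit_s = 0.5,
                                           x = m1[1], y = m1[2], z = m1[3],
                                           waveform_id = "w"),
                       waveforms = list(w = c(1, 0, 0)), config = cfg),
                  class = "scene")
  expect_error(render_audio(sc, mics, duration_s = 1), "coincides")
})

test_that("scene truth events sit on the emitter's trajectory", {
  cfg <- small_arena(seed = 9)
  sc <- simulate_scene(cfg, 3, 10, call_rate_hz = 0.4, render = FALSE)
  expect_gt(nrow(sc$events), 0)
  for (k in seq_len(nrow(sc$events))) {
    tr <- sc$trajectories[[sc$events$id[k]]]
    f <- round(sc$events$t_emit_s[k] * cfg$frame_rate_hz) + 1L
    expect_lt(sqrt(sum((tr$positions[f, ] -
                          c(sc$events$x[k], sc$events$y[k],
                            sc$events$z[k]))^2)), 1e-9)
  }
  pos <- do.call(rbind, lapply(sc$trajectories, function(t) t$positions))
  expect_true(all(pos[, 1] >= 0 & pos[, 1] <= cfg$length_m))
  expect_true(all(pos[, 2] >= 0 & pos[, 2] <= cfg$width_m))
  expect_true(all(pos[, 3] >= 0 & pos[, 3] <= cfg$height_m))
})

test_that("scene write/read round-trips field-for-field", {
  cfg <- small_arena(seed = 9)
  sc <- simulate_scene(cfg, 2, 4, call_rate_hz = 0.4, render = TRUE)
  d <- withr::local_tempdir()
  write_scene(sc, d)
  hdr <- strsplit(readLines(file.path(d, "tracks.csv"), n = 1), ",")[[1]]
  expect_identical(hdr, c("frame", "time_s", "id", "x_m", "y_m", "z_m"))
  sc2 <- read_scene(d)
  expect_identical(lapply(sc$trajectories, `[[`, "positions"),
                   lapply(sc2$trajectories, `[[`, "positions"))
  expect_identical(lapply(sc$trajectories, `[[`, "time_s"),
                   lapply(sc2$trajectories, `[[`, "time_s"))
  expect_identical(lapply(sc$trajectories, `[[`, "behavior"),
                   lapply(sc2$trajectories, `[[`, "behavior"))
  expect_identical(sc$events$t_emit_s, sc2$events$t_emit_s)
  expect_identical(sc$events$id, sc2$events$id)
  expect_identical(sc$config$mic_positions, sc2$config$mic_positions)
  # audio via float32: sample count exact, values at float32 precision
  expect_identical(ncol(sc2$audio$samples), ncol(sc$audio$samples))
  expect_identical(ncol(sc2$audio$samples),
                   as.integer(round(4 * cfg$audio_fs_hz)))
  expect_lt(max(abs(sc$audio$samples - sc2$audio$samples)), 1e-6)
  unlink(file.path(d, "events_truth.json"))
  expect_error(read_scene(d), "events_truth.json")
})
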