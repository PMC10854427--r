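# acoustic_localization: filter, detector, channel selection, TOADs,
# multilateration, jackknife, SNR

test_that("band-pass keeps the passband and kills the stopband", {
  fs <- 48000
  t <- (0:47999) / fs
  tone <- function(f) sin(2 * pi * f * t)
  au <- audio_block(rbind(tone(2000), tone(10000)), fs)
  out <- bandpass_filter(au, 1000, 4000)
  rms_in <- sqrt(mean(tone(2000)^2))
  expect_lt(abs(sqrt(mean(out$samples[1, ]^2)) / rms_in - 1), 0.01)
  atten_db <- 20 * log10(sqrt(mean(tone(10000)^2)) /
                           sqrt(mean(out$samples[2, ]^2)))
  expect_gte(atten_db, 40)
  # low = 0: pure low-pass, DC untouched
  dc <- audio_block(matrix(1, 1, 1000), fs)
  lp <- bandpass_filter(dc, 0, 4000)
  expect_lt(max(abs(lp$samples - 1)), 0.01)
  expect_error(bandpass_filter(au, 4000, 1000), "invalid band")
  expect_error(bandpass_filter(au, 1000, fs), "invalid band")
})

test_that("detector is quiet on noise and finds rendered calls", {
  fs <- 20000
  set.seed(42)
  noise <- audio_block(matrix(rnorm(60 * fs), 1), fs)
  expect_identical(nrow(detect_events(noise, k = 8)), 0L)
  expect_identical(nrow(detect_events(audio_block(matrix(0, 1, 0), fs))), 0L)

  cfg <- arena_config(audio_fs_hz = fs, seed = 5)
  mics <- mic_array(cfg$mic_positions, fs)
  wf <- synth_call_waveform(2000, 2, 0.15, 500, fs)
  sc <- structure(list(trajectories = list(),
                       events = data.frame(id = "b", t_emit_s = 1, x = 7,
                                           y = 3, z = 1, waveform_id = "w"),
                       waveforms = list(w = wf), config = cfg),
                  class = "scene")
  aud <- bandpass_filter(render_audio(sc, mics, snr_db = 20,
                                      duration_s = 2.5), 300, 8000)
  det <- detect_events(aud, channel = which.max(rowSums(aud$samples^2)))
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$t_start_s - 1), 0.04)     # truth onset + propagation
  expect_lt(abs(det$t_end_s - 1.15), 0.04)
})

test_that("events closer than the merge gap are fused", {
  fs <- 20000
  set.seed(1)
  x <- rnorm(fs) * 0.001
  burst <- synth_call_waveform(3000, 1, 0.02, 0, fs)
  x[2001:2400] <- x[2001:2400] + burst
  x[2501:2900] <- x[2501:2900] + burst       # 5 ms gap
  au <- audio_block(matrix(x, 1), fs)
  expect_identical(nrow(detect_events(au, window_s = 0.001,
                                      merge_gap_s = 0.01,
                                      min_duration_s = 0.005)), 1L)
  expect_identical(nrow(detect_events(au, window_s = 0.001,
                                      merge_gap_s = 0.001,
                                      min_duration_s = 0.005)), 2L)
})

test_that("channel selection ranks by SNR and enforces the minimum", {
  fs <- 20000
  cfg <- arena_config(audio_fs_hz = fs, seed = 5)
  mics <- mic_array(cfg$mic_positions, fs)
  src <- c(1, 1, 1)                          # near mic corner
  wf <- synth_call_waveform(2000, 1, 0.1, 0, fs)
  sc <- structure(list(trajectories = list(),
                       events = data.frame(id = "b", t_emit_s = 1,
                                           x = src[1], y = src[2],
                                           z = src[3], waveform_id = "w"),
                       waveforms = list(w = wf), config = cfg),
                  class = "scene")
  ev <- list(t_start_s = 1, t_end_s = 1.1)
  # noiseless render: every channel passes the threshold
  quiet <- render_audio(sc, mics, noise_rms = 1e-12, duration_s = 2)
  expect_setequal(select_channels(quiet, ev, min_snr_db = 6), 1:30)
  # noisy render: nearest mics rank first (SNR ~ 1/r^2)
  noisy <- render_audio(sc, mics, snr_db = 12, duration_s = 2)
  sel <- select_channels(noisy, ev, min_snr_db = 6, min_channels = 8)
  d <- sqrt(rowSums((mics$positions - rep(src, each = 30))^2))
  expect_true(all(sel[1:3] %in% order(d)[1:6]))
  # min_channels enforced even when few pass a harsh threshold
  sel2 <- select_channels(noisy, ev, min_snr_db = 90, min_channels = 8)
  expect_identical(length(sel2), 8L)
})

test_that("cross-correlation recovers an integer shift and is antisymmetric", {
  fs <- 1000
  set.seed(7)
  a <- rnorm(1000)
  b <- c(rep(0, 25), a[1:975])
  au <- audio_block(rbind(a, b), fs)
  ev <- list(t_start_s = 0.1, t_end_s = 0.9)
  tau <- estimate_toads(au, ev, c(1, 2), ref_channel = 1, max_lag_s = 0.05)
  expect_lt(abs(tau[2] - 25 / fs), 0.1 / fs)
  tau_swapped <- estimate_toads(au, ev, c(1, 2), ref_channel = 2,
                                max_lag_s = 0.05)
  expect_lt(abs(tau_swapped[1] + tau[2]), 0.1 / fs)
  silent <- audio_block(rbind(a, 0 * a), fs)
  expect_error(estimate_toads(silent, ev, c(1, 2), ref_channel = 1), "flat")
  expect_error(estimate_toads(au, ev, 1L), "at least 2")
})

test_that("multilateration recovers exact sources and flags degeneracy", {
  cfg <- arena_config()
  mics <- mic_array(cfg$mic_positions, cfg$audio_fs_hz)
  b <- arena_bounds(cfg)
  src <- c(cfg$length_m / 2, cfg$width_m / 2, 1.5)
  tau <- geometric_toads(src, mics)
  sol <- localize_source(tau, mics, b, ref = attr(tau, "ref"))
  expect_lt(sqrt(sum((sol$position - src)^2)), 1e-3)
  expect_false(sol$at_bounds)
  # optimality: residual no worse than at the true source
  res_true <- sqrt(mean(arenatrack:::toad_residuals(
    src, mics$positions, attr(tau, "ref"), tau,
    mics$speed_of_sound_m_s)[-attr(tau, "ref")]^2))
  expect_lte(sol$residual_rms_s, res_true + 1e-12)
  expect_error(localize_source(tau[1:3],
                               mic_array(mics$positions[1:3, ], 1e5), b),
               "4 receivers")
})

test_that("zero TOADs with a symmetric square array sit on the axis", {
  pos <- rbind(c(-1, -1, 2), c(1, -1, 2), c(1, 1, 2), c(-1, 1, 2),
               c(0, -1.4142135623730951, 2), c(0, 1.4142135623730951, 2))
  mics <- mic_array(pos, 1e5)
  b <- rbind(c(-2, -2, 0), c(2, 2, 2))
  sol <- localize_source(rep(0, 6), mics, b, ref = 1)
  expect_lt(max(abs(sol$position[1:2])), 1e-6)
  # never above the mic plane when bounds cap it
  expect_lte(sol$position[3], 2)
})

test_that("localization error grows monotonically with TOAD noise", {
  cfg <- arena_config()
  mics <- mic_array(cfg$mic_positions, cfg$audio_fs_hz)
  b <- arena_bounds(cfg)
  set.seed(31)
  sigmas <- c(0, 2e-5, 2e-4)
  med <- vapply(sigmas, function(s) {
    errs <- vapply(1:30, function(i) {
      src <- c(stats::runif(1, 1, 13), stats::runif(1, 1, 5.5),
               stats::runif(1, 0.2, 3.2))
      tau <- geometric_toads(src, mics)
      ref <- attr(tau, "ref")
      tau <- tau + stats::rnorm(30, 0, s)
      tau[ref] <- 0
      sol <- localize_source(tau, mics, b, ref = ref)
      sqrt(sum((sol$position - src)^2))
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("jackknife spread is near zero when exact and grows when corrupted", {
  cfg <- arena_config()
  mics <- mic_array(cfg$mic_positions[seq(1, 30, by = 3), ], 1e5)
  b <- arena_bounds(cfg)
  src <- c(4, 3, 1)
  tau <- geometric_toads(src, mics)
  ref <- attr(tau, "ref")
  clean <- jackknife_error(tau, mics, b, ref = ref)
  expect_lt(as.numeric(clean), 1e-3)
  bad <- tau
  victim <- setdiff(seq_along(tau), ref)[1]
  bad[victim] <- bad[victim] + 10 / 1e5
  corrupted <- jackknife_error(bad, mics, b, ref = ref)
  expect_gt(as.numeric(corrupted), as.numeric(clean))
  expect_error(jackknife_error(tau[1:4],
                               mic_array(mics$positions[1:4, ], 1e5), b),
               "5 receivers")
})

test_that("jackknife spread tracks the true error (rank correlation)", {
  cfg <- arena_config()
  mics <- mic_array(cfg$mic_positions[seq(1, 30, by = 3), ], 1e5)
  b <- arena_bounds(cfg)
  set.seed(57)
  n <- 200
  spread <- true_err <- numeric(n)
  for (i in seq_len(n)) {
    src <- c(stats::runif(1, 1, 13), stats::runif(1, 1, 5.5),
             stats::runif(1, 0.2, 3.2))
    tau <- geometric_toads(src, mics)
    ref <- attr(tau, "ref")
    tau <- tau + stats::rnorm(length(tau), 0, stats::runif(1, 0, 3e-4))
    tau[ref] <- 0
    sol <- localize_source(tau, mics, b, ref = ref)
    true_err[i] <- sqrt(sum((sol$position - src)^2))
    spread[i] <- as.numeric(jackknife_error(tau, mics, b, ref = ref))
  }
  rho <- stats::cor(spread, true_err, method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("SNR follows its power-ratio definition", {
  fs <- 10000
  set.seed(3)
  noise <- rnorm(2 * fs)
  sig <- noise
  sig[fs + 1:2000] <- sig[fs + 1:2000] + 10 * sin(2 * pi * 2000 *
                                                    (1:2000) / fs)
  au <- audio_block(matrix(sig, 1), fs)
  ev <- list(t_start_s = 1, t_end_s = 1.2)
  # amplitude 10x noise sigma: power ratio ~ 10^2 / 2 + 1 -> ~17 dB
  expect_lt(abs(compute_snr(au, ev, 1) -
                  10 * log10(1 + 100 / 2)), 1)
  quiet <- audio_block(matrix(noise, 1), fs)
  expect_lt(abs(compute_snr(quiet, ev, 1)), 0.5)   # event ~ noise: ~0 dB
  expect_error(compute_snr(au, list(t_start_s = 0.05, t_end_s = 0.3), 1),
               "pre-event")
  z <- audio_block(matrix(c(rep(0, 100), rnorm(100)), 1), 100)
  expect_error(compute_snr(z, list(t_start_s = 1.0, t_end_s = 1.99), 1),
               "zero power")
  # monotone in source amplitude
  snrs <- vapply(c(2, 5, 10), function(a) {
    s2 <- noise
    s2[fs + 1:2000] <- s2[fs + 1:2000] + a * sin(2 * pi * 2000 *
                                                   (1:2000) / fs)
    compute_snr(audio_block(matrix(s2, 1), fs), ev, 1)
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))
})
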