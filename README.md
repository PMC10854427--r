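# arenatrack

Analysis toolkit for large indoor animal-tracking arenas that combine a
ceiling microphone array with marker-based 3D motion capture — the kind of
"smart barn" used to study flocks of starlings or pigeons in a
14.7 m x 6.6 m x 3.8 m volume. The package covers the full offline
computational chain of such a facility:

* **Acoustic localization** — band-pass filtering, energy-envelope event
  detection on one channel, SNR-based channel selection, time-of-arrival
  difference (TOAD) estimation by cross-correlation with parabolic
  sub-sample refinement, bounded nonlinear least-squares multilateration,
  and a jackknife (leave-one-receiver-out) relative error estimate.
* **Sensor fusion** — 6-DOF rigid registration (Kabsch/SVD) of the acoustic
  frame into the motion-capture global frame from >= 4 paired
  measurements, and robust constant-offset timestamp alignment.
* **Trajectory analytics** — per-frame behavior classification (foraging
  below 0.5 m; perching between 0.5 and 3 m at < 1 m/s; flying above
  0.5 m at >= 1 m/s), synchronized foraging initiations chained at
  `dt` = 10 s, pairwise Jaccard behavioral similarity, and leadership
  networks from the directional-correlation-with-delay method
  (highly correlated segments, HCS).
* **Bioacoustics** — peak/center frequency, 90% bandwidth and duration,
  inflection points of the peak-frequency contour, aggregate entropy; PCA
  embedding of call features; assignment of localized calls to arena
  zones and to individuals (closest bird within 30 cm and the runner-up
  at least 50% farther).
* **Gaze reconstruction** — head-centric frame calibration from eye
  centers and beak tip, pose recovery from marker rigid bodies,
  median-roll/pitch horizon correction, marker-label swap repair (5 mm
  jump rule), lateral fovea rays at azimuth +/- 75 deg, and gaze-density
  maps on a 20 m sky dome (azimuth 0-360 deg, elevation 15-90 deg).
* **Closed-loop trials** — Y-maze geometry (92 cm x 27 cm arms at
  120 deg), a trial-controller state machine (settle -> haptic signal ->
  turn evaluation -> reward, with the 5 s detour-forgiveness rule), agent
  co-simulation, and exact cumulative binomial success statistics.
* **Synthetic arena** — a simulator that generates regime-switching bird
  trajectories (perch/forage/flight, optional leader-follower coupling)
  and renders physically consistent multichannel audio (sub-sample
  windowed-sinc delays, spherical 1/r spreading, calibrated SNR), so the
  entire pipeline is testable end-to-end with known ground truth and no
  recordings.

## The core statistic

A sound emitted at unknown position `x` reaches receiver `i` at distance
`d_i(x) = ||x - m_i||`. With a reference receiver `r` and measured TOADs
`tau_i`, the source estimate is

```
x* = argmin_x  sum_i [ (d_i(x) - d_r(x)) / c  -  tau_i ]^2
```

over the arena box (coarse 0.5 m grid seed, bounded L-BFGS-B, Gauss-Newton
polish). With 30 receivers the system is heavily over-determined, so
re-solving with each receiver left out once gives a per-event relative
error estimate (the jackknife spread).

## Worked example

```r
library(arenatrack)

cfg   <- arena_config(seed = 42)          # 14.68 x 6.62 x 3.83 m, 30 mics
scene <- simulate_scene(cfg, n_individuals = 3, duration_s = 12,
                        call_rate_hz = 0.4)
scene
#> <scene> 3 birds, 12 truth events, audio: 30 ch x 12.0 s

mics   <- mic_array(cfg$mic_positions, cfg$audio_fs_hz)
events <- localize_scene_audio(scene$audio, mics, arena_bounds(cfg))
nrow(events)                              # 12: every truth event localized
#> [1] 12

ev <- events[1, ]
sprintf("t = %.3f s at (%.2f, %.2f, %.2f) m, jackknife %.0f mm",
        ev$t_start_s, ev$x, ev$y, ev$z, 1000 * ev$jackknife_spread_m)
#> "t = 0.852 s at (12.82, 2.49, 1.50) m, jackknife 0 mm"

assign_individual(c(ev$x, ev$y, ev$z),
                  (ev$t_start_s + ev$t_end_s) / 2,
                  scene$trajectories)$id  # matches the emitter
#> [1] "bird02"
assign_zone(c(ev$x, ev$y, ev$z), cfg$zone_plan, arena_bounds(cfg))
#> [1] "perching"

round(table(classify_behavior(scene$trajectories[[1]])$label) / 1200, 3)
#>   flying foraging perching
#>    0.148    0.202    0.649
```

The call was detected, localized to the perch area with sub-centimeter
jackknife spread, and attributed to the correct bird purely from the
spatial proximity rules.

A command-line interface wraps the same pipeline
(`inst/cli/arenatrack <simulate|localize|register|classify|coordination|
features|assign|gaze|ymaze-sim|demo>`); every command writes a
provenance sidecar with the package version, seed and config hash.

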