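---
title: "arenatrack: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{arenatrack: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic arena does and does not
emulate, and the decisions made where the design was genuinely open. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. Acoustic source localization

**Model.** Sound from a point source at `x` propagates spherically at a
constant speed `c` (default 343 m/s, dry air at ~20 °C) to `n` fixed
receivers `m_i`. The observable is the vector of time-of-arrival
differences (TOADs) `tau_i` relative to a reference receiver. The source
estimate minimizes the sum of squared TOAD residuals over the arena box.
Assumptions: free-field propagation (no reverberation, no air
absorption), a synchronized single-clock acquisition chain, and a source
that is stationary over the correlation window. All three are idealized;
the jackknife spread is the instrument for noticing when they fail on a
given event.

**Numerics.** The cost surface has local minima (particularly a mirror
ambiguity through the receiver plane for a ceiling-only array), so the
solver seeds from the best node of a coarse grid (0.5 m — half the
smallest arena dimension scale at which distinct basins appear),
refines with bounded L-BFGS-B, and polishes interior solutions with a
few Gauss-Newton steps for quadratic terminal convergence. Supplying the
arena box as bounds removes the above-ceiling mirror solution by
construction; solutions pinned to a box face are flagged `at_bounds`.

**TOAD estimation.** Plain cross-correlation with 3-point parabolic
sub-sample interpolation is the default; ties between equal correlation
peaks break toward the smaller absolute delay. A PHAT (phase transform)
variant is available; its whitening is restricted to bins that carry
cross-spectral energy, because whitening a band-limited signal's empty
bins turns the correlation into noise. On the simulator, plain
correlation over the whole event proved more accurate than
onset-windowed or PHAT variants for both stationary and moving sources,
so it is the default (`toad_window_s = Inf`).

**Reference channel.** The loudest channel in the event window, mirroring
the feature pipeline's automatic loudest-channel pick.

**SNR definition.** The system's literature reports per-event SNR without
a formula; this package fixes it as `10*log10(P_event / P_noise)` with
`P_noise` taken from the adjacent pre-event window of equal length on the
band-passed signal. Detection thresholds and the channel-admission
threshold (6 dB) were calibrated on the simulator only.

**Jackknife error.** Each receiver is left out once; the spread is the
RMS distance of the leave-one-out solutions from their centroid. It is a
*relative* error: exact for detecting a single corrupted receiver,
correlated with — but not equal to — the true 3D error (tested as a rank
correlation, not a calibration).

## 2. Rigid registration and time alignment

Registration is the weighted Kabsch solution: SVD of the centered
cross-covariance with determinant correction, no scale factor (both
frames are metric; the pose has exactly 6 degrees of freedom). The field
protocol demands at least four paired measurements; three non-collinear
pairs are mathematically sufficient, so the package accepts three with a
warning and errors only on genuine degeneracy (collinear or coincident
points). The reported `rms_m` is the 3D fiducial registration error
`sqrt(mean ||R a_i + t - b_i||^2)`; for isotropic noise `sigma` on one
side it concentrates near `sigma * sqrt(3 - 6/n)`, which the tests check
by Monte Carlo. Correspondence weights are uniform by default — the two
systems have very different accuracies, but without a stated error model
there is no principled non-uniform choice; per-pair weights are
supported for users who have one.

Timestamp alignment assumes a constant clock offset (no drift) between
modalities: the offset candidate with the most co-occurring event-time
differences wins and is refined as the median of the matched
differences, which tolerates a substantial fraction of spurious or
missing events.

## 3. Trajectory behavior analytics

**Classification.** The published class rules use strict inequalities
that leave boundaries undefined; the package fixes half-open
conventions: foraging `z < 0.5`; flying `z >= 0.5 & v >= 1` (the speed
tie goes to flying); perching `0.5 <= z < 3 & v < 1`; and a residual
`other` class for `z >= 3 & v < 1`, which the source classes do not
cover. Height is the mo-cap `z` in meters above the floor. Speed is the
norm of the component-wise moving-average-smoothed central-difference
velocity; the 0.2 s smoothing window (unspecified upstream) is the
shortest that keeps marker jitter on a perched bird safely below the
1 m/s split at 100 Hz. Perching is height-and-speed only — whether the
original analysis additionally required proximity to the perch
structures is not stated, so the height-only rule is implemented.

**Foraging initiations.** Arrivals are transitions into the foraging
class, pooled over birds and chained while consecutive gaps stay below
10 s; a bird re-entering during an open chain extends the chain's clock
but is counted once. Event counts are non-increasing in the threshold
(a tested invariant).

**Directional correlation and HCS networks.** For unit flight-velocity
vectors, `C_ij(tau) = <v_i(t) . v_j(t+tau)>` over frames where both
birds fly (v >= 1 m/s), with `tau` at frame resolution. The HCS network
cuts the common timeline into consecutive non-overlapping windows
(default 2 s), calls a window highly correlated when
`max_tau C(tau) >= 0.9` with at least half the window in joint flight,
and weights each undirected edge by the summed HCS duration. The window,
delay range (±2 s) and threshold are package defaults — the upstream
method's exact values are not restated in the source material — and all
are exposed in the API. The overall Jaccard similarity is emitted in
both plausible conventions (ratio of sums across categories, and mean of
per-category indices), since the description is ambiguous between them.

## 4. Bioacoustic features and call assignment

Spectral quantiles (center frequency, 90% bandwidth, 90% duration) use
the discrete convention — the first bin at which cumulative power
reaches the target fraction — matching standard bioacoustic software;
a pure on-bin tone then yields `bandwidth90 <= 2` bins exactly. The
peak-frequency contour comes from a 512-sample Hann STFT with 75%
overlap, median-smoothed over 3 frames before counting slope sign
changes (both unspecified upstream; the median filter suppresses
single-frame bin flips that would otherwise inflate the inflection
count). Aggregate entropy is the Shannon entropy in bits of the
normalized mean STFT spectrum, the convention used by common
sound-analysis tools when a formula is not given.

Call-to-individual assignment applies two criteria at the event midpoint
(linear interpolation of each track; where in the call to anchor the
comparison was unstated, and the midpoint is the least biased choice for
a source that may move): the closest bird must be within 0.30 m and the
runner-up at least 1.5x farther. Zone assignment is purely spatial:
foraging for low positions over the foraging floor polygon, perching for
sub-3 m positions over the perch region, flight elsewhere in the box.

## 5. Gaze reconstruction

The head frame has its origin at the eye midpoint, +y toward the beak
tip, +x toward the right eye, +z up. Calibration stores the marker
template in head coordinates; each frame's pose is the rigid fit of that
template to the observed markers, which makes the calibration invariant
to any rigid motion of the calibration inputs (a tested equivariance).
Euler angles use intrinsic yaw (about z), then pitch (about the head's
x), then roll (about the head's y) — no convention is stated upstream,
so this one is documented on every angle interface. Horizon correction
subtracts the per-recording median roll and median pitch from every
frame, leaving yaw untouched.

Foveas project at azimuth ±75° (clockwise from the beak axis toward the
right eye) and elevation 0; the red area is a configurable
frontal-lower sector (default azimuth ±30°, elevation −90° to −10°,
10° grid) because the source describes it only qualitatively. Eye-in-head
movement (~5° in pigeons) is ignored: gaze is head-only.

The sky-dome histogram intersects each ray with the sphere of diameter
20 m about the group centroid (forward branch), bins azimuth 0–360° and
elevation 15–90°, and counts — rather than silently drops — rays below
the elevation band or originating outside the dome, so that bin mass
plus exclusions always equals the ray count. Bins weight by frame count;
frame rates here are uniform, so dwell-time weighting would be
proportional.

Marker-label repair cuts sections where any pairwise inter-marker
distance jumps by more than 5 mm between adjacent frames (missing
markers also cut), then picks per section the label permutation
minimizing total displacement across the boundary. A transposition of
markers `i` and `j` never changes `d(i, j)` itself nor the distance
between the other two markers, so detectability rests on the remaining
pairs: patterns whose transpositions all move some pair by well over
5 mm (as real ID patterns are designed to) repair exactly, while
near-symmetric patterns are genuinely ambiguous at this threshold —
boundaries that no permutation reconciles are flagged, not forced.

## 6. Closed-loop Y maze

Arms are 0.92 m x 0.27 m rectangles at 120°, labeled clockwise, with a
central junction disc, a mid-arm evaluation band (0.35–0.65 of arm
length; the physical evaluation points are not dimensioned upstream, so
mid-arm is the default and configurable) and a distal end band
(0.75–1.0). Turn side is computed geometrically from the bird's inward
heading, so consistent relabeling of arms cannot change outcomes.

The controller issues a haptic left/right signal after 0.5 s of
continuous dwell in an arm end (the settling time is unspecified
upstream; 0.5 s rejects fly-throughs at walking speeds), drawing sides
from balanced blocks of four (two lefts, two rights, shuffled) so that
short sessions stay near 50/50. The next crossing of another arm's
evaluation zone scores the turn; correct turns trigger a reward event.
A bird that returns to the signal arm within 5 s of leaving gets no new
signal and the detour is ignored; staying away longer than 5 s without
an evaluation, or exceeding the 30 s trial timeout, logs the signal as
missed. Hardware is replaced by log events; the stepping interface
mirrors the real-time contract and is co-simulated with scripted or
policy agents (an obedient agent is the oracle for success rate 1; a
coin-flipping agent converges to 0.5). `binomial_success` is the exact
upper-tail sum `P(X >= k)`, `X ~ Binomial(n, 1/2)`.

## 7. The synthetic arena: what it does and does not establish

The simulator is first-class, tested code, and the stated world for
every acceptance criterion.

*Geometry and rates.* 14.68 m x 6.62 m footprint, 3.83 m ceiling, 100 Hz
frames, 100 kHz audio, c = 343 m/s. The 30 receivers sit evenly along
the ceiling perimeter (inset 0.1 m) — the real array is described only
as fixed to the top frame, so any perimeter layout is admissible and
the layout is configurable.

*Trajectories.* Birds alternate perch bouts (exponential dwell, mean
20 s) and foraging bouts (mean 15 s) connected by curved flights
(quadratic Bezier, C2 smoothstep speed ramps, cruise 2–6 m/s); perch
jitter is zero-mean AR(1) with 5 mm standard deviation. Dwell means are
activity-compressed relative to a real aviary day so that short desk-
scale renders contain all three behaviors; the per-frame generating
regime is stored as ground truth, and the classifier agrees with it on
at least 99% of frames outside a ±0.5 s transition margin (the margin
covers the speed ramps through the 1 m/s threshold, which no
threshold-based classifier can attribute unambiguously). Flight-only
worlds use a correlated-heading wander (Ornstein-Uhlenbeck yaw rate,
~2.5 rad/s RMS — a 1.6 m turning radius at cruise, i.e. tight indoor
maneuvering) because delay estimation between leader and follower is
only identifiable when flight direction actually varies; followers copy
the leader's velocity delayed by `tau_f` plus isotropic noise.

*Audio.* Each call is delayed per channel by `distance/c` with a
windowed-sinc fractional-delay kernel (half-width 32, Hann window),
attenuated by spherical spreading `1/r`, and summed; white Gaussian
noise is calibrated so the requested per-event SNR (default 20 dB, the
reported operating point of such systems) holds at the nearest
microphone. Calls are harmonic stacks (fundamental ~1.8–2.6 kHz,
1–3 harmonics, mild chirps, ~0.18 s) matching reported starling-call
statistics; the default per-bird call rate (0.05 Hz, raised in demos) is
likewise desk-scale dense. Not emulated: reverberation, air absorption,
microphone directivity, Doppler (though motion during a call smears the
rendered delays exactly as physics dictates), and overlapping calls
(events are thinned to a 0.35 s minimum gap so the single-channel
detector's merge rule is exercised separately).

Consequently, a green end-to-end test establishes that the chain
detector -> channel selection -> TOADs -> multilateration -> assignment
is self-consistent under free-field physics at the stated SNR — not
that it would survive a reverberant barn; the headline biological
statistics of any real deployment depend on recordings this package
deliberately does not ship.

## 8. Known limitations

* The multilateration refinement assumes a single dominant source per
  event window; overlapping simultaneous calls are out of scope.
* PHAT weighting is provided but not default; on narrowband calls it
  underperforms plain correlation.
* Marker repair enumerates up to 6! label permutations per section;
  bodies with more than six markers are rejected rather than
  approximated.
* The controller's missed-trial semantics (abandon after a 5 s absence
  without evaluation, 30 s timeout) interpolate beyond the published
  description, which specifies only the no-new-signal detour rule; both
  windows are parameters.
* WAV I/O supports float32/float64/PCM16 — the subsets the toolkit
  writes or ingests — not the full RIFF zoo.
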