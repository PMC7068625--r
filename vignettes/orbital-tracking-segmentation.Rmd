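---
title: "Segmenting orbital-tracking trajectories into transport and stationary phases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting orbital-tracking trajectories into transport and stationary phases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbitrack)
```

## The data and the raw format

3D orbital tracking follows one fluorescent particle in real time: the
excitation beam orbits the particle, the phase and modulation of the
detected intensity give its position once per orbit, and the orbit is
recentered after every cycle. The instrument writes one plain-text file per
tracked particle: a labeled header block (orbit time, orbit radius, number
of dark orbits, long-range tracking settings, ...) followed by rows of 11
whitespace-delimited fields -- position in galvanometer volts (x, y, z),
orbit number, calculated orbit time, two per-orbit detector intensities,
camera frame, a tracking-active flag and two repositioning flags.

Three quirks of the format matter for analysis and are handled by
`read_orbit_file()` / `as_physical()`:

* **Dark orbits.** To limit photobleaching, every `delay_orbits`-th orbit is
  run with the laser off. Dark orbits receive an orbit number but are not
  written, so orbit numbers in the file have gaps and the effective
  sampling interval is `orbit_time_ms * (1 + delay_orbits)`
  (`effective_sampling_interval()`); 5 ms orbits with one dark orbit give
  the standard 10 ms resolution.
* **Long-range repositioning.** When the particle drifts beyond a preset
  galvanometer voltage (0.5882 V, i.e. 10.18 µm at the lateral calibration)
  the stage recenters it, which takes 30-70 ms. Stored positions are
  already corrected for these moves, so the converted trajectory is
  continuous; the affected rows are flagged and their orbit-time entry is
  enlarged.
* **Voltages, not micrometers.** All stored positions are hardware
  voltages. `as_physical()` multiplies by the calibration factors
  (`calibration()`, defaults 17.30 µm/V lateral and 10.00 µm/V axial).

**Column 5 semantics.** The format stores a "calculated orbit time" that
includes dark orbits and long-range events, without specifying whether it
is elapsed time or a per-record interval. We treat it as the interval since
the previous written record, because that is where individual dark-orbit
and repositioning gaps naturally live, and build timestamps as its
cumulative sum anchored at `t_ms[1] = 0`. Files that store elapsed time
instead are handled by `as_physical(time_mode = "elapsed")`, which anchors
the stored values at zero without summing.

Other reader-level decisions: rows with a wrong field count are format
errors naming the row; non-monotone orbit numbers are a warning (real
instruments glitch), never silent; points flagged tracking-inactive (search
mode) are excluded from analysis by default because their positions are
meaningless; repositioning-flagged points are kept because their positions
are already corrected; files declaring more than one tracking channel are
rejected as unsupported rather than guessing the column multiplexing. On
write, voltages get 6 decimal places and times 3, which exceeds instrument
resolution and makes write-read round trips exact at the documented
precision.

## The segmentation model

The biological picture is two-state: a mitochondrion either pauses
(tethered, wiggling isotropically) or is carried by motors along the axon
(persistent direction, roughly constant speed). The discriminating signal
is directional persistence of consecutive displacements, not displacement
magnitude -- which is why this analysis is less biased by localization
noise than a mean-squared-displacement classification of the same windows.

Let the reference axis be the unit chord from the first to the last xy
position (`reference_axis()`; z is ignored as axial displacement is small
compared to lateral). Φ(t) is the signed angle in (−π, π] between
displacement t and that axis (`lateral_angles()`). The windowed correlation
(`correlation_carpet()`) over a window of τ_max angles is

$$\mathrm{Cor}(t,\tau)=\frac{1}{\tau_{max}-\tau}
\sum_{i=t}^{t+\tau_{max}-\tau-1}\Phi(i)\,\Phi(i+\tau),
\qquad \tau = 1,\dots,\tau_{max}-1,$$

and the amplitude is $A(t)=\sum_\tau \mathrm{Cor}(t,\tau)$
(`correlation_amplitude()`). During a pause the angles are independent and
uniform, so every product averages to zero; during a run with mean angle
$\bar\Phi \neq 0$ every lag converges to $\bar\Phi^2$ and
$A \approx (\tau_{max}-1)\,\bar\Phi^2$.

Two normalization choices are deliberate and documented as switches:

* **Per-lag normalization.** Each lag τ sums exactly τ_max − τ products
  (upper summation index `t + τ_max − τ − 1`, so every index stays inside
  the window) and is divided by that count, making lags comparable,
  unbiased window means. The alternative global reading -- dividing every
  lag by `n − τ` with `n` the full series length -- is available as
  `norm = "global"`; it rescales each lag by a constant and does not change
  which windows cross a threshold computed with the same normalization.
* **Lag 0 is excluded** from the amplitude: it is a pure power term
  (mean of Φ²) that is large for any angle series and carries no
  information about temporal persistence.

### The randomization threshold

How large can $A$ get by chance? The null is estimated per trajectory
(`randomized_threshold()`): shuffle the angle series, recompute the
amplitude, and repeat `n_shuffles` times. Because a trajectory with a large
net displacement has an angle distribution that is already biased toward
the chord direction, shuffling alone would build that bias into the null;
the series is therefore first symmetrized by appending its negative copy
(−Φ, the mirror image of the track across the reference axis), which makes
the augmented sample mean exactly zero. With $M$ and $\sigma$ the mean and
standard deviation of all pooled shuffled amplitude values,

$$T = M + w\,\sigma .$$

`w = 5` is the standard operating point; the tests verify that it keeps the
false-transport rate on i.i.d. angle series below 1% of windows.
How many shuffles, and whether $M,\sigma$ come from one or many
randomizations, is an open choice; we pool over 100 permutations by default
so that $T$ itself has low seed-to-seed variance, and expose
`n_shuffles`. Windows with $A(t) > T$ (strictly; ties are stationary) are
transport, and each maximal run of transport windows is one event with
distance, duration and velocity (`segment_motion()`, or the whole pipeline
via `analyze_track()`).

### From windows to points, and the minimum event length

A window statistic must be anchored to a trajectory point. Window start `t`
is mapped to the center of the data that produced it,
`t + τ_max/2 + smooth_points/2` (`alignment = "center"`; `"start"` is
available). Consequently segment boundaries inherit an uncertainty of
roughly half a window.

Near a true boundary the amplitude passes gradually through `T`, and noise
makes it cross back and forth, which would fragment one run into many
sub-window events. Since an event shorter than the correlation window
cannot be resolved by a τ_max-window statistic in the first place, runs of
labels shorter than `min_windows` (default τ_max/2) are iteratively
absorbed into their surroundings, shortest first. Setting `min_windows = 1`
disables the filter.

### Smoothing for noise-dominated steps

At 10 ms sampling, a mitochondrion at 0.5-2 µm/s moves 5-20 nm per
interval, while the localization precision of in vivo recordings can be
tens of nm. Consecutive-point angles are then angles of noise vectors:
nearly uniform regardless of motion state, and no threshold can separate
the states (the per-window signal is bounded by
$(\tau_{max}-1)\bar\Phi^2$ with $\bar\Phi \to 0$). The pipeline therefore
computes angles on lag-m displacements `p[i+m] − p[i]`
(`smooth_points = m`, default 16 in `analyze_track()`), which is identical
to differencing an m-point moving average of the positions: the drift per
displacement grows m-fold while its noise stays constant, so the
displacement signal-to-noise ratio improves by a factor m, at the cost of
blurring boundaries by about m/2 points. The default 16 brings the
worst-case step SNR of the scenarios above (≈ 0.07 at 0.5 µm/s, 50 nm
noise) above 1. For recordings whose steps already exceed the localization
precision, `smooth_points = 1` reproduces the raw consecutive-orbit
analysis.

### Distance and velocity of an event

Summed point-to-point path length is the conventional "distance traveled",
but under localization noise it measures mostly noise: with 50 nm jitter
and 5-20 nm steps the raw path length is inflated several-fold, and any
velocity derived from it would be meaningless. Event `distance_um` is
therefore the net xy displacement between the event's end points -- an
accurate measure for motor-driven runs, which are straight on the event
scale -- and `velocity_um_per_s = distance_um / duration`. The raw path
length is still reported as `path_length_um` for completeness.

### Degenerate inputs and numerical conventions

* Zero-length displacements (a perfectly stalled particle) have no
  direction; their angle is defined as 0 and flagged `zero_step`.
* Antiparallel displacements get Φ = +π, never −π (the (−π, π] convention).
* A trajectory with zero net xy displacement has no chord; this is an
  error instructing the caller to pass an explicit `axis`.
* An all-zero angle series gives M = σ = 0 and thus T = 0 exactly.
* Carpet rows are computed from cumulative sums (O(n τ_max) total); the
  test suite pins them to a naive double-loop oracle at float precision,
  with error measured relative to the scale of a single angle product
  because windowed sums can cancel to ~0.
* `analyze_track(seed = )` makes the permutation null reproducible without
  touching the caller's RNG state.

## What the simulator emulates -- and what it does not

`simulate_trajectory()` builds positions from a `segment_plan()` (runs:
constant-speed steps along a per-segment heading, optionally with per-step
heading wobble; pauses: zero drift, optionally a small random walk since
real paused mitochondria wiggle), then adds isotropic Gaussian localization
noise to every position. Jitter is applied to positions, not displacements,
because localization error -- not diffusion -- dominates orbital-tracking
noise. `write_raw_trajectory()` exports to the raw dialect: volts, dark-orbit
numbering gaps, synthetic constant intensities, and long-range repositioning
events timed by an internally simulated galvanometer offset; written
voltages are the stage-corrected continuous positions, as in real files, so
the round trip back through `as_physical()` reproduces the generated
positions at write precision.

Default conditions mirror the standard acquisition: 5 ms orbits with one
dark orbit (10 ms effective interval), 0.5882 V long-range threshold,
30-70 ms repositioning pauses, 50 nm localization noise, run speeds of
0.4-2 µm/s. The scenario presets use curved-axon ("switchback") geometry
with run headings 55-75° off the chord, and the randomized recovery
scenarios draw an even number of alternating ±θ runs with equal per-run
displacements so the chord stays on the bisector and every run's realized
chord offset equals its planned heading.

The simulator does **not** emulate photophysics (bleaching, activation
kinetics, photon-level orbit intensities), z motion, diffusive transport
states, or tracking loss, and its localization noise is white whereas a
real feedback tracker's error is slightly autocorrelated. Passing the
recovery tests therefore demonstrates correctness of the estimator under
the stated noise/geometry model, not performance on arbitrary real
recordings -- in particular not on trajectories whose transport direction
coincides with the chord (below).

## Operating envelope and known limitations

The detector keys on a sustained non-zero mean angle. Its per-window signal
is at most $(\tau_{max}-1)\bar\Phi^2$, while the null spread of the
amplitude scales with the angle variance of the whole trace; for a
pause-dominated trace (pause angles uniform, variance π²/3) at τ_max = 64
and w = 5 the threshold sits near 30, so a run needs a sustained mean
angle of roughly 45° off the chord to be detectable, less when transport
dominates the trace (which shrinks the shuffled variance). Consequences:

* **Chord-aligned transport is invisible.** A straight run parallel to the
  chord has $\bar\Phi \approx 0$ and is missed by construction. This is
  intrinsic to using the trajectory chord as reference; the analysis is
  informative for curved paths. For suspected chord-aligned runs, re-run
  with an explicit rotated `axis` as a diagnostic.
* Boundaries carry ±(τ_max + m)/2-point uncertainty; events must exceed
  `min_windows` windows to be reported.
* The null is estimated per trajectory; very short trajectories
  (barely above τ_max + m points) give noisy thresholds.
* With `smooth_points = m`, neighboring angles share no noise terms but do
  share drift, so the carpet's small-lag structure partly reflects the
  smoothing; the permutation null, computed on the same smoothed series,
  accounts for this.

## Problem sizes used by the tests

The test suite and acceptance script run on simulated data sized for tight
feedback cycles while still exercising every code path at the standard
parameters (τ_max = 64, w = 5, 100 shuffles): oracle comparisons on 100
random series up to n = 1000 with τ_max ∈ {32, 64, 128}; null specificity
on 50 replicates of 300 i.i.d. angles; recovery on 20 randomized
curved-axon scenarios of roughly 1500-3000 points each; raw-format round
trips on 100 files of 20-240 records. These sizes are the package's chosen
verification conditions; all of them scale linearly if larger studies are
wanted.
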